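---
title: "Cytoband copy-number alteration analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytoband copy-number alteration analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnascan)
```

# The problem

SNP-array profiling of tumor tissue yields, per sample, tens of thousands of
log2 copy-number ratios along the genome (0 = diploid).  Three features of
such data shape everything this package does:

1. **Copy number is locally constant.**  Losses and gains happen in
   segments — typically cytobands, arms or whole chromosomes — so
   neighboring SNPs share the same underlying copy number and per-probe
   noise can be averaged away.
2. **Tumor tissue is admixed.**  The assayed DNA mixes tumor cells with
   stroma and other normal cells.  If a fraction $\alpha$ (the *purity*) of
   cells carry an event with integer copy number $c$, the expected log2
   ratio is not $\log_2(c/2)$ but
   $$\mu(c, \alpha) = \log_2\!\frac{\alpha c + (1-\alpha)\,2}{2},$$
   pulled toward 0.  A single hard threshold on raw values therefore
   misses real events ("partial" gains and losses), which motivates
   statistic-based smoothing and scoring rather than raw-value cutoffs.
3. **Cohort questions live at the cytoband/arm level.**  Recurrence across
   tumors, differences between clinical groups, survival association and
   subtype structure are all asked of regions, not individual probes.

The pipeline is: smooth each profile with moving-window t statistics;
summarize each sample into signed cytoband scores; call events and
aggregate to arms; pool frequencies across studies; compare groups; scan
for survival association; cluster samples.  Chromosome X and Y are excluded
throughout (sex-linked dosage would otherwise confound every stage), so all
coordinates live on autosomes 1–22, p arm before q arm.

# Smoothing: moving-window t statistics

`moving_t_smooth()` replaces each SNP's raw value with the one-sample
t-statistic of the `window_snps` (default 31) raw values centered on it,
tested against 0.  The default window matches the scale at which the local
constancy assumption is safe on a 100K-density array.  Decisions the
statistic itself does not dictate:

* **Null value.**  The test is against 0 on the log2 scale, i.e. against
  the diploid state — the smoothing exists to detect departures from two
  copies.
* **Chromosome boundaries.**  Windows never span chromosomes; local
  constancy has no meaning across a boundary.  Near a chromosome end the
  window shrinks symmetrically, but not below `min_window` (default 5)
  values: below that the window is extended asymmetrically inward, so that
  even terminal SNPs are smoothed by at least `min_window` observations.
* **Zero variance.**  A window of identical values has an infinite
  t-statistic; the output is 0 for an all-zero window and otherwise
  `sign(mean) * zero_variance_cap` (default 50 — large enough to dominate
  the downstream ±10 call cutoff, finite so sums and averages stay
  defined).  This arises only in noiseless synthetic data.

Each output is computed from its own window (full windows via a running
filter, edge windows by direct summation), so changing one raw value
changes at most `window_snps` outputs, and the statistic is scale-free:
multiplying a profile by a positive constant leaves the smoothed profile
unchanged (bit-exact for binary-representable factors).

# Cytoband scores

`summarize_cytobands()` reduces each sample's smoothed profile to one
signed score per cytoband: positive = gain, negative = loss.  Two regional
tests are offered.  The default, `"t"`, is the one-sample t-statistic of
the band's smoothed values against 0; `"binomial"` is the signed sign-test
z, $(n_+ - n/2)/\sqrt{n/4}$ over the band's nonzero values.  The t variant
is the default because the downstream constants — the ±10 call cutoff and
the 2.5 IQR floor — are meaningful on the scale of a t statistic computed
over tens of SNPs, and they are kept at those conventional values here.

Bands with fewer than two SNPs cannot support either test; their SNPs are
merged into the neighboring band toward the centromere (with a message).
On the synthetic backbone this never triggers; with real sub-band cytoband
files it keeps every emitted band testable.

Quartiles — used by the box summaries (`group_box_summary()`) and by the
IQR gate (`score_iqr()`) — use linear interpolation between order
statistics (R's type 7).  The convention is fixed and documented because
the IQR feeds a hard threshold: alternative quartile rules move the IQR of
small cohorts by more than the 2.5 cutoff's slack.

A band-score property worth stating: under the null the band t-scores do
*not* have unit variance, because the smoothed values inside a band are
autocorrelated at the window scale.  Empirically their null spread is
about 4–5, which is why the call cutoff of 10 (roughly two null SDs) and
the IQR floor of 2.5 behave sensibly on this scale.

# Event calls, arms, and pooled frequencies

`call_cytobands()` applies strict thresholds: score > 10 is a gain,
score < −10 a loss, everything else neutral.  `arm_summary()` aggregates:
an arm's loss (gain) proportion across a group is the *maximum* band-level
loss (gain) proportion within the arm, the arm's overall direction is
whichever proportion is larger, and an exact tie is left undecided.

`pool_counts()` pools published per-study event counts by summing events
and totals — fixed pooling with no heterogeneity model, treating counts
from different detection platforms as exchangeable.  Percentages are
rounded half away from zero; this rounding reproduces every printed
percentage of the packaged six-study table (`read_study_counts()`).

# Group comparison and event correlation

`compare_groups()` is Welch's unequal-variance two-sample t per cytoband
with Welch–Satterthwaite degrees of freedom — group sizes in this setting
are habitually unequal, so the pooled-variance t would be mis-calibrated.
Significance is declared on the raw statistic at |t| > 2 (the
`stat_threshold` default); a Benjamini–Hochberg column is emitted for
reference but deliberately does not drive the flag, keeping the flag's
semantics those of a fixed-statistic screen.  If both groups have zero
variance and equal means the statistic is defined as 0.

`correlate_events()` reduces each sample to a per-event intensity (mean
score over the event's bands, sign-oriented so that larger always means
more of the event) and reports the Pearson correlation with its two-sided
t-based p-value.

# Disease-specific survival and the resampled scan

`build_dss()` encodes disease-specific survival: time runs from the first
operation to disease-caused death (event) or to the last follow-up
(censored); death from an unrelated cause censors at the death date.

`cox_score_test()` is a single-covariate Cox partial-likelihood score test,
written out in full in the package: score $U(0)$ and information $I(0)$
with Breslow handling of ties, statistic $U(0)^2/I(0)$ against
$\chi^2_1$, and the reported coefficient from a damped one-dimensional
Newton ascent (steps clamped to ±2, estimate capped at ±20 when the
likelihood is monotone — near-separated data have no finite maximum).
For a binary covariate with untied event times the statistic coincides
with the logrank chi-square, which the test suite exploits as an
independent oracle.  A constant covariate is degenerate by contract:
statistic 0, p 1, coefficient 0.

`resampled_scan()` runs the per-band survival screen:

* bands whose cross-sample score IQR is ≤ 2.5 are excluded as carrying no
  variation worth testing;
* each included band is tested in `n_models` (default 100) Cox models, each
  on a random patient subset of `round(subset_fraction * n)` patients drawn
  *without replacement* (default fraction 0.8 — the subset size is a
  package choice surfaced in the configuration, resampling rather than
  bootstrap because each model should see each patient at most once);
* per band, the −log10 p-values and coefficients are averaged over the
  non-degenerate models (subsets with no events or constant covariates are
  skipped and `n_models_used` reports the survivors).

Subset draws come from a substream keyed on the seed and the *band name*,
so results are invariant to both sample order and band order.  p-values
are carried in log space, so extreme associations do not underflow to
`-log10(0)`.

One calibration subtlety is worth knowing when reading scan output.  Under
a null (no association), each model's p-value is uniform, so the per-band
*mean* of −log10 p has expectation $1/\ln 10 \approx 0.434$, and averaging
that mean across bands estimates 0.434 well.  But because the models of
one band share ~80% of their patients, the 100 values averaged per band
are strongly correlated: the per-band mean does not concentrate, its
across-band distribution stays right-skewed, and its *median* sits nearer
$-\log_{10} 0.5 \approx 0.30$.  The averaging buys robustness to
influential patients, not extra degrees of freedom.

# Clustering and subtype recovery

`cluster_samples()` performs agglomerative hierarchical clustering of
score-matrix rows.  The default distance is the correlation distance
(1 − r between sample score profiles) with Ward linkage.  This default is
a deliberate choice made after testing the obvious alternative: alteration
scores scale jointly with tumor purity and event breadth, so with
euclidean distance a group of tumors sharing broad (whole-chromosome)
events is split by purity before groups are separated by signature — on
the packaged subtype cohort euclidean/Ward recovers only ~65% of subtype
labels while correlation/Ward recovers ~98–100%.  Euclidean distance and
average/complete linkage remain available.

`mapped_accuracy()` scores a clustering against known classes under the
best one-to-one cluster-to-class matching, solved exactly as an assignment
problem (Hungarian algorithm); extra clusters beyond the number of classes
count all their members as errors.  The result is invariant to any
relabeling on either side.

# The synthetic-data generator

`simulate_cohort()` generates the testbed every stage is validated on.
Per sample: each of its group's events is realized independently with its
penetrance; purity is drawn uniformly from `purity_range`; SNPs under an
event with tumor copy number $c$ get mean $\mu(c, \alpha)$ as above, all
SNPs get i.i.d. Gaussian noise.  Choices and what they emulate:

* **Noise sd 0.25** on the log2 scale — a typical mid-range per-probe noise
  level for SNP arrays of this class; there is no authoritative per-study
  value, so it is a package default and configurable.
* **Purity range (0.4, 0.9)** by default — assayed tumor tissue is rarely
  pure, and early-stage tumors tend to run lower; the packaged templates
  restrict to (0.6, 0.9) so planted events stay clearly separated from
  noise in ground-truth tests.
* **Event boundaries snap to cytobands** (arm and whole-chromosome regions
  being unions of bands); sub-band breakpoints are out of scope.
* **Survival link**: exponential event times with log hazard =
  log(baseline) + Σ coef × carrier-status; censoring is applied per sample
  with probability `censor_rate`, observed at a uniform fraction of the
  event time.
* **Templates.**  `stage_template_spec()` encodes the earliest-stage
  signature (−3p, +5q, +7, −14) against the latest-stage signature (those
  plus −1p, +1q, −6q, −8p, +8q, −9, +12, −13, −18, +20, −22), penetrance
  0.8, 40 tumors per group.  `subtype_template_spec()` encodes the four
  RCC subtype signatures (clear cell: −3p, +5q, −8p, −14q; papillary: +7,
  +12, +3p, +16, +17; chromophobe: broad losses; oncocytoma: none) at
  penetrance 1 — it models between-subtype separation, not within-subtype
  heterogeneity.

What the generator does *not* emulate: allele-specific states, subclonal
mixtures of more than two cell populations, probe-specific response,
GC/wave artifacts, or translocations (a translocation is represented only
by its copy-number consequence).  Passing tests on this testbed therefore
demonstrate the pipeline's correctness and its behavior under admixture
and noise — not robustness to array artifacts that the generator does not
produce.

# Problem sizes and numerical conventions

The packaged experiments run on a synthetic backbone of 22 autosomes ×
2 arms × 3 cytobands × 60 SNPs (7,920 loci, 132 bands) — a 1/12-scale
stand-in for a 100K chip that preserves the band-to-window ratio the
method depends on.  Cohorts are 40 tumors per group for call-recovery
experiments, 200 tumors for survival recovery, and 10 per subtype for
clustering.  Conventions: coordinates are 0-based half-open internally
(the UCSC cytoband dialect); band names are "3p25"-style without a "chr"
prefix; all readers normalize row order to genome order; score files
round-trip at full double precision.

# Known limitations

* The regional score scale depends on band SNP counts and the smoothing
  window; the ±10 cutoff and the 2.5 IQR floor are calibrated for
  t-scores over tens of SNPs and should be revisited for arrays or band
  maps with very different density.
* Fixed pooling of published counts ignores between-study heterogeneity
  and platform differences, by design.
* The survival scan fits one covariate per model; no clinical adjusters.
* The resampled scan's averaged −log10 p is a ranking statistic, not a
  calibrated p-value (see the calibration note above).
* With heavily imbalanced carrier fractions (penetrance near 0 or 1),
  survival associations are underpowered at desk-scale cohort sizes; the
  packaged survival cohort uses penetrance 0.5 for exactly this reason.
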