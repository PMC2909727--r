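Package: cnascan
Title: Cytogenetic Copy-Number Alteration Scanning for SNP-Array Tumor Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for cytoband-level copy-number alteration
    analysis of SNP-array log2-ratio profiles from admixed tumor samples:
    moving-window t-statistic smoothing, regional (cytoband) alteration
    scoring, tri-state event calling with arm-level aggregation, cross-study
    frequency pooling, two-group comparison, a resampled Cox score-test
    survival scan, and unsupervised subtype clustering.  Includes a
    tumor/normal admixture simulator that generates cohorts with known
    segmental events, purity, noise, and survival links, so every stage can
    be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    ape,
    survival,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
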