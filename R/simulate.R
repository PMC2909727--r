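#' Segmental copy-number event specification
#'
#' Describes one integer-copy-number event a tumor may carry: the region
#' (whole chromosome, arm, cytoband or band range; see [region_bands()]),
#' the tumor-cell copy number (0 or 1 = loss, 3+ = gain; 2 is not an event),
#' and the penetrance -- the probability that a sample of the group carries
#' the event.
#'
#' @param region region string, e.g. `"3p"`, `"7"`, `"5q3"`, `"5q2:5q3"`.
#' @param tumor_cn non-negative integer copy number in the tumor cells.
#' @param penetrance carrier probability in \[0, 1\].
#' @param label event label for reports; defaults to the "-3p"/"+5q" style
#'   derived from the sign of the change.
#' @return An `event_spec` list.
#' @export
event_spec <- function(region, tumor_cn, penetrance = 1, label = NULL) {
  stopifnot(length(region) == 1L, is.character(region))
  tumor_cn <- as.integer(tumor_cn)
  if (tumor_cn < 0L) stop("tumor_cn must be non-negative")
  if (tumor_cn == 2L) stop("tumor_cn 2 is diploid, not an event")
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
  if (is.null(label)) {
    label <- paste0(if (tumor_cn < 2L) "-" else "+", region)
  }
  structure(list(region = region, tumor_cn = tumor_cn,
                 penetrance = penetrance, label = label),
            class = "event_spec")
}

#' Cohort simulation specification
#'
#' A cohort is a set of groups (subtype/stage strata), each with its own
#' event set, plus global admixture and noise parameters and an optional
#' survival link.  Tumor purity -- the fraction of assayed cells that are
#' tumor cells -- attenuates every event toward the diploid log-ratio 0,
#' which is what produces "partial" gains and losses in admixed tissue.
#'
#' @param groups list of groups; each a list with `label`, `subtype`,
#'   `stage`, `n`, and `events` (list of [event_spec()]).
#' @param purity_range length-2 numeric in (0, 1]; per-sample purity is drawn
#'   uniformly from it.  Default `c(0.4, 0.9)`.
#' @param noise_sd per-SNP Gaussian noise sd on the log2 scale (default
#'   0.25).
#' @param survival optional list with `baseline_hazard` (events per day),
#'   `coefficients` (named numeric: per-event-label log hazard ratios for
#'   carriers), and `censor_rate` in \[0, 1).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups, purity_range = c(0.4, 0.9), noise_sd = 0.25,
                        survival = NULL) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  for (g in groups) {
    if (!all(c("label", "subtype", "stage", "n", "events") %in% names(g))) {
      stop("each group needs label, subtype, stage, n, events")
    }
    if (g$n < 1L) stop("group '", g$label, "' has n < 1")
  }
  if (length(purity_range) != 2L || any(purity_range <= 0) ||
      any(purity_range > 1) || purity_range[1L] > purity_range[2L]) {
    stop("purity_range must be an interval within (0, 1]")
  }
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(survival)) {
    if (is.null(survival$baseline_hazard) || survival$baseline_hazard <= 0) {
      stop("survival$baseline_hazard must be > 0")
    }
    if (is.null(survival$censor_rate)) survival$censor_rate <- 0
    if (survival$censor_rate < 0 || survival$censor_rate >= 1) {
      stop("survival$censor_rate must be in [0, 1)")
    }
    if (is.null(survival$coefficients)) survival$coefficients <- numeric(0)
  }
  structure(list(groups = groups, purity_range = purity_range,
                 noise_sd = noise_sd, survival = survival),
            class = "cohort_spec")
}

#' Simulate one admixed SNP profile
#'
#' For a SNP covered by an event with tumor copy number `c` the expected
#' log2 ratio under tumor purity `a` is `log2((a*c + (1-a)*2) / 2)`; SNPs
#' outside every event have expectation 0.  I.i.d. Gaussian noise of sd
#' `noise_sd` is added everywhere.  Events must be pairwise non-overlapping
#' in SNP space.
#'
#' @param genome a `genome_map` with SNP loci.
#' @param events list of [event_spec()] realized for this sample.
#' @param purity tumor purity in (0, 1].
#' @param noise_sd Gaussian noise sd (>= 0; 0 gives the noiseless mean).
#' @param sample_id sample identifier.
#' @return An [snp_profile()].
#' @export
simulate_profile <- function(genome, events, purity, noise_sd = 0.25,
                             sample_id = "sim") {
  stopifnot(inherits(genome, "genome_map"), n_snps(genome) > 0L)
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  mu <- numeric(n_snps(genome))
  seen <- logical(n_snps(genome))
  for (ev in events) {
    idx <- region_snps(genome, ev$region)
    if (any(seen[idx])) stop("overlapping events at region '", ev$region, "'")
    seen[idx] <- TRUE
    mu[idx] <- log2((purity * ev$tumor_cn + (1 - purity) * 2) / 2)
  }
  values <- mu + stats::rnorm(length(mu), sd = noise_sd)
  snp_profile(sample_id, values, genome)
}

#' Simulate a full cohort with ground truth
#'
#' Realizes each group's events independently per sample at their
#' penetrance, draws purity uniformly from the spec's range, simulates the
#' admixed noisy profile, and (if a survival link is specified) draws
#' disease-specific survival from an exponential model whose log hazard is
#' `log(baseline_hazard) + sum(coef[label] * carrier)`.  Censored samples
#' (probability `censor_rate`, independent) are observed at a uniform
#' fraction of their event time.  Fully reproducible: set the RNG seed
#' before calling.
#'
#' @param genome a `genome_map` with SNP loci.
#' @param spec a [cohort_spec()].
#' @return List with `profiles` (list of [snp_profile()]), `annotations`
#'   (a [sample_annotations()] data.frame), `survival` (data.frame
#'   `sample_id`, `duration`, `event`, or `NULL`), and `truth` (data.frame
#'   `sample_id`, `group`, `label`, `region`, `tumor_cn`, `carrier`).
#' @export
simulate_cohort <- function(genome, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$survival) && length(spec$survival$coefficients)) {
    all_labels <- unlist(lapply(spec$groups,
                                function(g) vapply(g$events, `[[`, "", "label")))
    unknown <- setdiff(names(spec$survival$coefficients), all_labels)
    if (length(unknown)) {
      stop("survival coefficient for unknown event label '", unknown[1L], "'")
    }
  }
  profiles <- list()
  ann <- list()
  truth <- list()
  surv <- list()
  k <- 0L
  for (g in spec$groups) {
    for (i in seq_len(g$n)) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", g$label, i)
      carrier <- vapply(g$events, function(ev) {
        stats::runif(1) < ev$penetrance
      }, logical(1L))
      purity <- stats::runif(1, spec$purity_range[1L], spec$purity_range[2L])
      profiles[[k]] <- simulate_profile(genome, g$events[carrier], purity,
                                        spec$noise_sd, sample_id = sid)
      ann[[k]] <- data.frame(
        sample_id = sid, subtype = g$subtype, stage = g$stage,
        grade = if (is.null(g$grade)) "unknown" else g$grade,
        size_cm = NA_real_, purity = purity, stringsAsFactors = FALSE
      )
      if (length(g$events)) {
        truth[[k]] <- data.frame(
          sample_id = sid, group = g$label,
          label = vapply(g$events, `[[`, "", "label"),
          region = vapply(g$events, `[[`, "", "region"),
          tumor_cn = vapply(g$events, function(e) e$tumor_cn, 0L),
          carrier = carrier, stringsAsFactors = FALSE
        )
      }
      if (!is.null(spec$survival)) {
        coefs <- spec$survival$coefficients
        lab <- vapply(g$events, `[[`, "", "label")
        lp <- 0
        if (length(coefs)) {
          hit <- intersect(names(coefs), lab[carrier])
          lp <- sum(coefs[hit])
        }
        rate <- spec$survival$baseline_hazard * exp(lp)
        t_event <- stats::rexp(1, rate)
        censored <- stats::runif(1) < spec$survival$censor_rate
        surv[[k]] <- data.frame(
          sample_id = sid,
          duration = if (censored) stats::runif(1, 0, t_event) else t_event,
          event = !censored, stringsAsFactors = FALSE
        )
      }
    }
  }
  annotations <- sample_annotations(do.call(rbind, ann))
  list(
    profiles = profiles,
    annotations = annotations,
    survival = if (length(surv)) do.call(rbind, surv) else NULL,
    truth = if (length(truth)) do.call(rbind, truth) else
      data.frame(sample_id = character(0), group = character(0),
                 label = character(0), region = character(0),
                 tumor_cn = integer(0), carrier = logical(0))
  )
}

#' Read a cohort specification from YAML
#'
#' The YAML mirrors [cohort_spec()]: top-level `purity_range`, `noise_sd`,
#' optional `survival` (`baseline_hazard`, `censor_rate`, `coefficients` as
#' a label->value map), and `groups`, each with `label`, `subtype`, `stage`,
#' `n_samples` and `events` (each event: `region`, `tumor_cn`, optional
#' `penetrance`, `label`).  The group size key is spelled `n_samples`
#' because a bare `n` is a YAML 1.1 boolean.
#'
#' @param path YAML file path.
#' @return A [cohort_spec()].
#' @export
read_cohort_spec_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read cohort specs from YAML")
  }
  y <- yaml::read_yaml(path)
  groups <- lapply(y$groups, function(g) {
    if (!is.null(g$n_samples)) g$n <- g$n_samples
    g$events <- lapply(g$events, function(e) {
      event_spec(e$region, e$tumor_cn,
                 penetrance = if (is.null(e$penetrance)) 1 else e$penetrance,
                 label = e$label)
    })
    g
  })
  survival <- y$survival
  if (!is.null(survival) && !is.null(survival$coefficients)) {
    survival$coefficients <- unlist(survival$coefficients)
  }
  cohort_spec(
    groups = groups,
    purity_range = if (is.null(y$purity_range)) c(0.4, 0.9)
                   else as.numeric(y$purity_range),
    noise_sd = if (is.null(y$noise_sd)) 0.25 else y$noise_sd,
    survival = survival
  )
}

#' Stage-signature cohort template
#'
#' The packaged two-group ccRCC template used for integration testing: the
#' earliest-stage signature (S1a: -3p, +5q, +7, -14) against the
#' latest-stage signature (S3b4, which adds -1p, +1q, -6q, -8p, +8q, -9,
#' +12, -13, -18, +20, -22).  Purity is restricted to (0.6, 0.9) so planted
#' events stay well separated from noise.
#'
#' @param n_per_group samples per stage group (default 40).
#' @param penetrance carrier probability for every planted event (default
#'   0.8).
#' @param purity_range purity interval (default `c(0.6, 0.9)`).
#' @param noise_sd per-SNP noise sd (default 0.25).
#' @param survival optional survival link, as in [cohort_spec()].
#' @return A [cohort_spec()] with groups `S1a` and `S3b4`.
#' @export
stage_template_spec <- function(n_per_group = 40L, penetrance = 0.8,
                                purity_range = c(0.6, 0.9), noise_sd = 0.25,
                                survival = NULL) {
  ev <- function(region, cn) event_spec(region, cn, penetrance)
  s1a <- list(ev("3p", 1L), ev("5q", 3L), ev("7", 3L), ev("14", 1L))
  s3b4 <- c(s1a, list(
    ev("1p", 1L), ev("1q", 3L), ev("6q", 1L), ev("8p", 1L), ev("8q", 3L),
    ev("9", 1L), ev("12", 3L), ev("13", 1L), ev("18", 1L), ev("20", 3L),
    ev("22", 1L)
  ))
  cohort_spec(
    groups = list(
      list(label = "S1a", subtype = "CC", stage = "S1a", n = n_per_group,
           events = s1a),
      list(label = "S3b4", subtype = "CC", stage = "S3b4", n = n_per_group,
           events = s3b4)
    ),
    purity_range = purity_range, noise_sd = noise_sd, survival = survival
  )
}

#' Subtype-signature cohort template
#'
#' Four RCC subtype groups with their characteristic copy-number signatures:
#' clear cell (CC: -3p, +5q, -8p, -14q), papillary (PA: +7, +12, +3p, +16,
#' +17), chromophobe (CH: broad losses of 1, 2, 6, 10, 13, 17), and
#' oncocytoma (ON: no recurrent events).  Used for clustering and
#' subtype-recovery tests.  Every sample carries its subtype's full
#' signature by default (penetrance 1): the template emulates signature
#' separation between subtypes, not within-subtype event heterogeneity.
#'
#' @param n_per_group samples per subtype (default 10).
#' @param penetrance carrier probability per event (default 1).
#' @param purity_range purity interval (default `c(0.6, 0.9)`).
#' @param noise_sd per-SNP noise sd (default 0.25).
#' @return A [cohort_spec()] with groups CC, PA, CH, ON.
#' @export
subtype_template_spec <- function(n_per_group = 10L, penetrance = 1,
                                  purity_range = c(0.6, 0.9), noise_sd = 0.25) {
  ev <- function(region, cn) event_spec(region, cn, penetrance)
  cohort_spec(groups = list(
    list(label = "CC", subtype = "CC", stage = "unknown", n = n_per_group,
         events = list(ev("3p", 1L), ev("5q", 3L), ev("8p", 1L), ev("14q", 1L))),
    list(label = "PA", subtype = "PA", stage = "unknown", n = n_per_group,
         events = list(ev("7", 3L), ev("12", 3L), ev("3p", 3L), ev("16", 3L),
                       ev("17", 3L))),
    list(label = "CH", subtype = "CH", stage = "unknown", n = n_per_group,
         events = list(ev("1", 1L), ev("2", 1L), ev("6", 1L), ev("10", 1L),
                       ev("13", 1L), ev("17", 1L))),
    list(label = "ON", subtype = "ON", stage = "unknown", n = n_per_group,
         events = list())
  ), purity_range = purity_range, noise_sd = noise_sd)
}
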