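#' Disease-specific survival record
#'
#' Builds the survival endpoint used for prognosis: time from the first
#' operation to death (an event only when the death is disease-caused) or
#' to the last known follow-up (censored).  Death from an unrelated cause
#' censors the record at the death date.
#'
#' @param operation_date,death_date,last_followup_date `Date` or
#'   `"YYYY-MM-DD"` strings; `death_date` may be `NA` (alive).
#' @param cause_is_disease logical: was the death caused by the disease?
#' @param sample_id sample identifier.
#' @return List with `sample_id`, `duration` (days), `event` (logical).
#' @export
build_dss <- function(operation_date, death_date, last_followup_date,
                      cause_is_disease, sample_id = "sample") {
  op <- as.Date(operation_date)
  dd <- if (is.null(death_date) || is.na(death_date)) NA else as.Date(death_date)
  fu <- as.Date(last_followup_date)
  end <- if (!is.na(dd)) dd else fu
  if (is.na(end)) stop("no end date for sample '", sample_id, "'")
  if (end < op) stop("end date precedes operation date for sample '", sample_id, "'")
  list(
    sample_id = sample_id,
    duration = as.numeric(end - op),
    event = !is.na(dd) && isTRUE(cause_is_disease)
  )
}

#' Single-covariate Cox score test
#'
#' Partial-likelihood score test of a single continuous covariate in a Cox
#' proportional-hazards model, with Breslow handling of tied event times.
#' The statistic is `U(0)^2 / I(0)` referred to a chi-square distribution
#' with 1 degree of freedom, where `U` and `I` are the partial-likelihood
#' score and information at coefficient 0.  The reported coefficient is the
#' maximum partial-likelihood estimate from a one-dimensional Newton fit.
#' For a binary covariate the score statistic coincides with the logrank
#' chi-square (when event times are untied).
#'
#' A constant covariate (or one with no information among the at-risk
#' samples) is degenerate: the test returns statistic 0, p-value 1,
#' coefficient 0, with `degenerate = TRUE`.
#'
#' @param x numeric covariate, one value per sample.
#' @param time non-negative follow-up durations.
#' @param event logical (or 0/1) event indicators; at least one event.
#' @return List with `statistic`, `p_value`, `log10_p` (log10 of the
#'   p-value, exact even when the p-value underflows), `coefficient`,
#'   `degenerate`.
#' @export
cox_score_test <- function(x, time, event) {
  n <- length(x)
  stopifnot(length(time) == n, length(event) == n)
  event <- as.logical(event)
  if (any(time < 0)) stop("negative survival time")
  if (!any(event)) stop("no events in the survival data")
  if (stats::sd(x) == 0) {
    return(list(statistic = 0, p_value = 1, log10_p = 0, coefficient = 0,
                degenerate = TRUE))
  }
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  ui <- cox_score_info(x, time, event, beta = 0)
  if (!is.finite(ui$info) || ui$info <= 0) {
    return(list(statistic = 0, p_value = 1, log10_p = 0, coefficient = 0,
                degenerate = TRUE))
  }
  stat <- ui$score^2 / ui$info
  log_p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE, log.p = TRUE)
  beta <- cox_newton_fit(x, time, event)
  list(statistic = stat, p_value = exp(log_p), log10_p = log_p / log(10),
       coefficient = beta, degenerate = FALSE)
}

# Score U(beta) and information I(beta) of the Cox partial likelihood
# (Breslow ties); inputs sorted by ascending time.
cox_score_info <- function(x, time, event, beta) {
  w <- exp(beta * x)
  # suffix sums: S*(t_i) over the risk set {j : time_j >= time_i}
  s0 <- rev(cumsum(rev(w)))
  s1 <- rev(cumsum(rev(w * x)))
  s2 <- rev(cumsum(rev(w * x * x)))
  # risk set at a tied time starts at the first index of that time
  first <- match(time, time)
  e <- which(event)
  r <- first[e]
  mu <- s1[r] / s0[r]
  list(score = sum(x[e] - mu),
       info = sum(s2[r] / s0[r] - mu * mu))
}

cox_newton_fit <- function(x, time, event, max_iter = 30L, tol = 1e-9,
                           beta_cap = 20) {
  beta <- 0
  for (iter in seq_len(max_iter)) {
    ui <- cox_score_info(x, time, event, beta)
    if (!is.finite(ui$info) || ui$info <= 0) break
    step <- ui$score / ui$info
    if (!is.finite(step)) break
    step <- max(min(step, 2), -2)  # damp wild early steps
    beta <- beta + step
    if (abs(beta) > beta_cap) {
      beta <- sign(beta) * beta_cap  # monotone likelihood: report capped fit
      break
    }
    if (abs(step) < tol) break
  }
  beta
}

#' Resampled per-cytoband survival scan
#'
#' Associates each cytoband's alteration scores with disease-specific
#' survival, robustly to individual influential patients: bands whose
#' cross-sample score IQR is at most `iqr_min` are excluded as
#' uninformative; for each remaining band, `n_models` Cox models are fitted
#' on random patient subsets of size `round(subset_fraction * n)` (drawn
#' without replacement, a fresh draw per model), the score-test p-value of
#' the band score is transformed to `-log10(p)`, and the transformed
#' p-values and fitted coefficients are averaged over the non-degenerate
#' models (a model is degenerate when its subset has no events or a
#' constant covariate).
#'
#' The subset stream for each band is derived deterministically from `seed`
#' and the band name, so the scan is invariant to sample order and to band
#' order.
#'
#' @param scores a [score_matrix()].
#' @param records data.frame with `sample_id`, `duration`, `event` covering
#'   the score matrix's samples.
#' @param iqr_min IQR inclusion threshold (default 2.5).
#' @param n_models models per band (default 100).
#' @param subset_fraction fraction of patients per model, in (0, 1\]
#'   (default 0.8).
#' @param seed integer seed for the subset draws.
#' @return data.frame in score-matrix column order: `band`, `included`,
#'   `mean_neglog10_p`, `mean_coefficient`, `n_models_used`.
#' @export
resampled_scan <- function(scores, records, iqr_min = 2.5, n_models = 100L,
                           subset_fraction = 0.8, seed = 1L) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "duration", "event") %in% names(records)))
  if (subset_fraction <= 0 || subset_fraction > 1) {
    stop("subset_fraction must be in (0, 1]")
  }
  if (n_models < 1L) stop("n_models must be >= 1")
  missing <- setdiff(rownames(scores), records$sample_id)
  if (length(missing)) stop("no survival record for sample '", missing[1L], "'")
  # canonical sample order: sorted ids, so the scan is order invariant
  ids <- sort(rownames(scores))
  sc <- scores[ids, , drop = FALSE]
  rec <- records[match(ids, records$sample_id), , drop = FALSE]
  n <- length(ids)
  m <- as.integer(round(subset_fraction * n))
  if (m < 3L) stop("subset size ", m, " is too small (< 3)")
  if (sum(rec$event) * subset_fraction < 2) {
    stop("fewer than 2 events expected per subset")
  }
  out <- data.frame(
    band = colnames(sc), included = FALSE, mean_neglog10_p = NA_real_,
    mean_coefficient = NA_real_, n_models_used = 0L,
    row.names = NULL, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(sc))) {
    if (score_iqr(sc, colnames(sc)[j]) <= iqr_min) next
    out$included[j] <- TRUE
    set.seed(band_substream_seed(seed, colnames(sc)[j]))
    neglog10 <- numeric(0)
    coefs <- numeric(0)
    for (b in seq_len(n_models)) {
      idx <- sample.int(n, m)
      if (!any(rec$event[idx]) || stats::sd(sc[idx, j]) == 0) next
      fit <- cox_score_test(sc[idx, j], rec$duration[idx], rec$event[idx])
      if (fit$degenerate) next
      neglog10 <- c(neglog10, -fit$log10_p)
      coefs <- c(coefs, fit$coefficient)
    }
    out$mean_neglog10_p[j] <- mean(neglog10)
    out$mean_coefficient[j] <- mean(coefs)
    out$n_models_used[j] <- length(neglog10)
  }
  out
}

# deterministic per-band substream seed (band-name hash keeps the scan
# invariant to band order; kept well below 2^31)
band_substream_seed <- function(seed, band_name) {
  h <- 0
  for (code in utf8ToInt(band_name)) h <- (h * 31 + code) %% 1000003
  as.integer((abs(as.numeric(seed)) %% 1000) * 1000003 + h)
}
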