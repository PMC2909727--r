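# Independent brute-force oracles used to validate the package's numerical
# kernels.  These deliberately take the slow, explicit path (per-window
# loops, risk-set enumeration, textbook formulas) so they share no code with
# the implementations they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny genome for unit tests
tiny_genome <- function(bands_per_arm = 2L, snps_per_band = 10L) {
  make_genome(bands_per_arm = bands_per_arm, snps_per_band = snps_per_band)
}

# moving-window t oracle: explicit window per SNP, t via stats::t.test
oracle_moving_t <- function(values, chrom, window, min_window = 5L, cap = 50) {
  out <- numeric(length(values))
  half <- (window - 1L) %/% 2L
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    for (k in seq_len(m)) {
      h <- min(half, k - 1L, m - k)
      lo <- k - h; hi <- k + h
      if (hi - lo + 1L < min_window) {
        lo <- max(1L, min(k - (min_window - 1L) %/% 2L, m - min_window + 1L))
        hi <- lo + min_window - 1L
      }
      w <- values[idx[lo:hi]]
      if (stats::sd(w) == 0) {
        out[idx[k]] <- if (mean(w) == 0) 0 else sign(mean(w)) * cap
      } else {
        out[idx[k]] <- unname(stats::t.test(w, mu = 0)$statistic)
      }
    }
  }
  out
}

# type-7 quantile oracle: manual linear interpolation between order stats
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

oracle_iqr <- function(x) oracle_quantile7(x, 0.75) - oracle_quantile7(x, 0.25)

# one-sample band t oracle via stats::t.test
oracle_band_t <- function(v) unname(stats::t.test(v, mu = 0)$statistic)

# sign-test z oracle, algebraically rearranged form
oracle_sign_z <- function(v) (2 * sum(v > 0) - length(v)) / sqrt(length(v))

# Welch t oracle via stats::t.test
oracle_welch_t <- function(a, b) unname(stats::t.test(a, b)$statistic)

# Pearson r oracle from the raw sum formula
oracle_pearson_r <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Cox partial-likelihood score and information at beta = 0 by explicit
# risk-set enumeration (Breslow ties)
oracle_cox_UI <- function(x, time, event) {
  U <- 0
  I <- 0
  for (i in which(as.logical(event))) {
    risk <- which(time >= time[i])
    xbar <- mean(x[risk] * 1)          # beta = 0: weights all 1
    s0 <- length(risk)
    s1 <- sum(x[risk])
    s2 <- sum(x[risk]^2)
    U <- U + x[i] - s1 / s0
    I <- I + s2 / s0 - (s1 / s0)^2
  }
  list(U = U, I = I)
}

# logrank chi-square oracle (no ties assumed: one event per event time)
oracle_logrank <- function(group, time, event) {
  stopifnot(all(group %in% c(0, 1)))
  O_minus_E <- 0
  V <- 0
  for (t in sort(time[as.logical(event)])) {
    risk <- which(time >= t)
    died <- which(time == t & as.logical(event))
    n <- length(risk)
    n1 <- sum(group[risk] == 1)
    d <- length(died)
    d1 <- sum(group[died] == 1)
    O_minus_E <- O_minus_E + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O_minus_E^2 / V
}

# best label-to-class matching by brute force over all injective mappings
oracle_mapped_accuracy <- function(labels, truth) {
  lab <- as.integer(factor(labels))
  tru <- as.integer(factor(truth))
  counts <- table(lab, tru)
  kl <- nrow(counts); kt <- ncol(counts)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  k <- max(kl, kt)
  best <- 0
  for (p in perms(seq_len(k))) {
    total <- 0
    for (i in seq_len(kl)) {
      j <- p[i]
      if (j <= kt) total <- total + counts[i, j]
    }
    best <- max(best, total)
  }
  best / length(labels)
}

# direct access to the regional scoring kernel
band_score_for_test <- function(v, method) cnascan:::band_score(v, method)

# deterministic cohort under a fixed seed
simulate_cohort_seeded <- function(genome, spec, seed) {
  set.seed(seed)
  simulate_cohort(genome, spec)
}
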