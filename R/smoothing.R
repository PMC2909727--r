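#' Moving-window t-statistic smoothing
#'
#' Replaces each raw per-SNP log2 ratio with the one-sample t-statistic of
#' the values in a window centered on it, tested against 0 (the diploid
#' log2 ratio).  Copy-number change is locally constant -- neighboring SNPs
#' share the same underlying copy number -- so pooling a window of neighbors
#' sharpens real segmental shifts while averaging out per-probe noise.
#'
#' Windows never span a chromosome boundary.  Near a chromosome end the
#' window shrinks symmetrically, but never below `min_window`: once the
#' symmetric window would fall below that, it is extended asymmetrically
#' within the chromosome to exactly `min_window` SNPs.
#'
#' If a window has zero standard deviation the t-statistic is undefined; the
#' output is 0 when the window mean is 0, otherwise `sign(mean) *
#' zero_variance_cap`.
#'
#' @param profile an [snp_profile()] bound to `genome`.
#' @param genome a `genome_map` with SNP loci.
#' @param window_snps odd window width in SNPs (default 31).
#' @param min_window odd minimum window width at chromosome ends (default 5).
#' @param zero_variance_cap finite magnitude substituted for the infinite
#'   t-statistic of a zero-variance window (default 50; large enough to
#'   dominate the downstream +/-10 call cutoff).
#' @return An object of class `smoothed_profile` (same shape as
#'   `snp_profile`: `sample_id` plus per-SNP `values`).
#' @export
moving_t_smooth <- function(profile, genome, window_snps = 31L,
                            min_window = 5L, zero_variance_cap = 50) {
  stopifnot(inherits(genome, "genome_map"), n_snps(genome) > 0L)
  window_snps <- as.integer(window_snps)
  min_window <- as.integer(min_window)
  if (window_snps < 1L || window_snps %% 2L == 0L) stop("window_snps must be odd and positive")
  if (min_window < 3L || min_window %% 2L == 0L) stop("min_window must be odd and >= 3")
  if (min_window > window_snps) stop("min_window must be <= window_snps")
  if (zero_variance_cap <= 0) stop("zero_variance_cap must be > 0")
  x <- profile$values
  if (length(x) != n_snps(genome)) {
    stop("profile '", profile$sample_id, "' is not aligned to the genome map")
  }
  out <- numeric(length(x))
  half <- (window_snps - 1L) %/% 2L
  min_half <- (min_window - 1L) %/% 2L
  for (ch in unique(genome$snps$chrom)) {
    idx <- which(genome$snps$chrom == ch)
    m <- length(idx)
    if (m < min_window) {
      stop("chromosome ", ch, " has only ", m, " SNPs (< min_window = ",
           min_window, ")")
    }
    xi <- x[idx]
    i <- seq_len(m)
    h <- pmin(half, i - 1L, m - i)
    lo <- i - h
    hi <- i + h
    narrow <- (hi - lo + 1L) < min_window
    if (any(narrow)) {
      lo[narrow] <- pmax(1L, pmin(i[narrow] - min_half, m - min_window + 1L))
      hi[narrow] <- lo[narrow] + min_window - 1L
    }
    n <- hi - lo + 1L
    # window sums are taken per window (filter for full windows, direct sums
    # at chromosome ends), so each output depends only on its own window
    s1 <- numeric(m)
    s2 <- numeric(m)
    full <- n == window_snps & h == half
    if (any(full)) {
      f1 <- stats::filter(xi, rep(1, window_snps), sides = 2)
      f2 <- stats::filter(xi * xi, rep(1, window_snps), sides = 2)
      s1[full] <- f1[i[full]]
      s2[full] <- f2[i[full]]
    }
    for (k in which(!full)) {
      w <- xi[lo[k]:hi[k]]
      s1[k] <- sum(w)
      s2[k] <- sum(w * w)
    }
    mean_w <- s1 / n
    var_w <- pmax(0, (s2 - s1 * s1 / n) / (n - 1L))
    # a window that is constant in exact arithmetic can leave a tiny
    # positive residual through the cumulative sums; treat it as zero
    var_w[var_w <= (s2 / n) * 1e-13] <- 0
    sd_w <- sqrt(var_w)
    t_w <- ifelse(sd_w > 0, mean_w / (sd_w / sqrt(n)),
                  ifelse(mean_w == 0, 0, sign(mean_w) * zero_variance_cap))
    out[idx] <- t_w
  }
  structure(list(sample_id = profile$sample_id, values = out),
            class = "smoothed_profile")
}

#' @export
print.smoothed_profile <- function(x, ...) {
  cat("smoothed_profile '", x$sample_id, "': ", length(x$values), " SNPs\n",
      sep = "")
  invisible(x)
}

#' Smooth every profile of a cohort
#'
#' @param profiles list of [snp_profile()].
#' @inheritParams moving_t_smooth
#' @return List of `smoothed_profile`.
#' @export
smooth_cohort <- function(profiles, genome, window_snps = 31L,
                          min_window = 5L, zero_variance_cap = 50) {
  lapply(profiles, moving_t_smooth, genome = genome,
         window_snps = window_snps, min_window = min_window,
         zero_variance_cap = zero_variance_cap)
}
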