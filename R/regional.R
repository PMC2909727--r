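#' Cytoband-level alteration scores
#'
#' Summarizes each sample's smoothed profile into one signed score per
#' cytoband (positive = gain, negative = loss), by testing whether the
#' band's smoothed values sit collectively above or below zero:
#'
#' * method `"t"` (default): one-sample t-statistic of the band's smoothed
#'   values against 0;
#' * method `"binomial"`: signed z from a sign test,
#'   `(n_pos - n/2) / sqrt(n/4)` where `n_pos` counts values > 0 and `n`
#'   the values that are nonzero (exact zeros are uninformative ties and
#'   are dropped; they cannot occur on smoothed data).
#'
#' Cytobands with fewer than 2 SNPs cannot support either test; their SNPs
#' are merged into the neighboring band toward the centromere (next band on
#' the p arm, previous band on the q arm), with a message.
#'
#' @param smoothed list of `smoothed_profile` (from [moving_t_smooth()]).
#' @param genome a `genome_map` with SNP loci.
#' @param method `"t"` or `"binomial"`.
#' @return A [score_matrix()] (samples x cytobands, columns in genome
#'   order).
#' @export
summarize_cytobands <- function(smoothed, genome, method = c("t", "binomial")) {
  method <- match.arg(method)
  stopifnot(inherits(genome, "genome_map"), n_snps(genome) > 0L,
            length(smoothed) >= 1L)
  assign_band <- merge_small_bands(genome)
  keep <- sort(unique(assign_band))
  groups <- split(seq_len(n_snps(genome)), factor(assign_band, levels = keep))
  nm <- genome$bands$name[keep]
  scores <- matrix(0, nrow = length(smoothed), ncol = length(keep),
                   dimnames = list(vapply(smoothed, `[[`, "", "sample_id"), nm))
  for (i in seq_along(smoothed)) {
    v <- smoothed[[i]]$values
    if (length(v) != n_snps(genome)) {
      stop("profile '", smoothed[[i]]$sample_id,
           "' is not aligned to the genome map")
    }
    scores[i, ] <- vapply(groups, function(idx) band_score(v[idx], method), 0)
  }
  score_matrix(scores, method = method)
}

band_score <- function(v, method) {
  n <- length(v)
  if (method == "binomial") {
    # sign test: exact zeros are uninformative ties and are dropped
    n_pos <- sum(v > 0)
    n_eff <- n_pos + sum(v < 0)
    if (n_eff == 0L) return(0)
    return((n_pos - n_eff / 2) / sqrt(n_eff / 4))
  }
  m <- mean(v)
  s <- stats::sd(v)
  if (s == 0) return(0)
  m / (s / sqrt(n))
}

# Reassign SNPs of bands with < 2 SNPs to the neighbor toward the
# centromere; returns a per-SNP band row index.  Errors if a band ends up
# empty with no neighbor to take it.
merge_small_bands <- function(genome) {
  bands <- genome$bands
  assign_band <- genome$snps$band
  counts <- tabulate(assign_band, nbins = nrow(bands))
  small <- which(counts > 0L & counts < 2L)
  for (j in small) {
    target <- if (bands$arm[j] == "p") j + 1L else j - 1L
    if (target < 1L || target > nrow(bands) ||
        bands$chrom[target] != bands$chrom[j]) {
      # no within-chromosome neighbor toward the centromere: fall back to
      # the other direction
      target <- if (bands$arm[j] == "p") j - 1L else j + 1L
    }
    if (target < 1L || target > nrow(bands) ||
        bands$chrom[target] != bands$chrom[j]) {
      stop("cytoband '", bands$name[j], "' has < 2 SNPs and no neighbor to merge into")
    }
    message("merging cytoband '", bands$name[j], "' (", counts[j],
            " SNP) into '", bands$name[target], "'")
    assign_band[assign_band == j] <- target
  }
  # cascaded merges could still leave a band under 2 SNPs only if a whole
  # chromosome holds < 2 SNPs
  counts <- tabulate(assign_band, nbins = nrow(bands))
  if (any(counts > 0L & counts < 2L)) {
    bad <- which(counts > 0L & counts < 2L)[1L]
    stop("cytoband '", bands$name[bad], "' still has < 2 SNPs after merging")
  }
  assign_band
}

#' Cross-sample interquartile range of a cytoband's scores
#'
#' IQR (third minus first quartile, quartiles by linear interpolation
#' between order statistics -- the "type 7" rule) of one band's column of a
#' score matrix.  This is the variability measure that gates the survival
#' scan: bands whose scores barely vary across samples carry no prognostic
#' signal to test.
#'
#' @param scores a [score_matrix()] with >= 2 samples.
#' @param cytoband cytoband name (a column of `scores`).
#' @return The interquartile range (numeric scalar).
#' @export
score_iqr <- function(scores, cytoband) {
  if (nrow(scores) < 2L) stop("score IQR needs >= 2 samples")
  if (!cytoband %in% colnames(scores)) stop("unknown cytoband '", cytoband, "'")
  q <- stats::quantile(scores[, cytoband], c(0.25, 0.75), names = FALSE, type = 7)
  q[2L] - q[1L]
}
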