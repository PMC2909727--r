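#' Per-group box summary of cytoband scores
#'
#' For one group of samples, the first quartile, median and third quartile
#' of every cytoband's scores (quartiles by linear interpolation, type 7),
#' emitted in genome order.  A band whose whole box sits below zero
#' (`q3 < 0`) is flagged `majority_loss` -- at least 75% of the group's
#' samples have a negative score there -- and symmetrically `majority_gain`
#' when `q1 > 0`.
#'
#' @param scores a [score_matrix()].
#' @param members character vector of sample ids (>= 2) forming the group.
#' @param group_label label attached to the output.
#' @return data.frame with `band`, `q1`, `median`, `q3`, `flag` (one of
#'   `"majority_loss"`, `"majority_gain"`, `"none"`), `group`, `n`.
#' @export
group_box_summary <- function(scores, members, group_label = "group") {
  missing <- setdiff(members, rownames(scores))
  if (length(missing)) stop("unknown sample '", missing[1L], "'")
  if (length(members) < 2L) stop("box summary needs >= 2 group members")
  sub <- scores[members, , drop = FALSE]
  q <- apply(sub, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
             names = FALSE, type = 7)
  flag <- ifelse(q[3L, ] < 0, "majority_loss",
                 ifelse(q[1L, ] > 0, "majority_gain", "none"))
  data.frame(
    band = colnames(scores), q1 = q[1L, ], median = q[2L, ], q3 = q[3L, ],
    flag = flag, group = group_label, n = length(members),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Two-group cytoband comparison (studentized test)
#'
#' Welch's unequal-variance two-sample t test per cytoband, with
#' Welch-Satterthwaite degrees of freedom.  A band is flagged significant
#' when `|t|` exceeds `stat_threshold` (default 2); this is the raw-statistic
#' rule used throughout the analysis.  A Benjamini-Hochberg adjusted p-value
#' column is emitted alongside for reference but does not drive the flag.
#'
#' If both groups have zero variance on a band and equal means, the
#' statistic is defined as 0.
#'
#' @param scores a [score_matrix()].
#' @param group_a,group_b character vectors of sample ids (each >= 2).
#' @param stat_threshold significance threshold on `|t|` (default 2).
#' @return data.frame in genome order with `band`, `t`, `df`, `p_value`,
#'   `p_adj` (BH), `significant`.
#' @export
compare_groups <- function(scores, group_a, group_b, stat_threshold = 2) {
  if (stat_threshold <= 0) stop("stat_threshold must be > 0")
  for (g in list(group_a, group_b)) {
    missing <- setdiff(g, rownames(scores))
    if (length(missing)) stop("unknown sample '", missing[1L], "'")
    if (length(g) < 2L) stop("both groups need >= 2 samples")
  }
  a <- scores[group_a, , drop = FALSE]
  b <- scores[group_b, , drop = FALSE]
  na <- nrow(a); nb <- nrow(b)
  ma <- colMeans(a); mb <- colMeans(b)
  va <- apply(a, 2L, stats::var); vb <- apply(b, 2L, stats::var)
  se2 <- va / na + vb / nb
  t_stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2),
                   ifelse(ma == mb, 0, sign(ma - mb) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)),
               na + nb - 2)
  p <- ifelse(is.finite(t_stat), 2 * stats::pt(-abs(t_stat), df), 0)
  p[t_stat == 0] <- 1
  data.frame(
    band = colnames(scores), t = t_stat, df = df, p_value = p,
    p_adj = stats::p.adjust(p, method = "BH"),
    significant = abs(t_stat) > stat_threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Correlation between two copy-number events
#'
#' Measures, across samples, the Pearson correlation between the intensity
#' of two events (e.g. 3p loss vs 5q gain).  Per sample, each event's
#' intensity is the mean score over its band set, oriented by the event's
#' sign so that larger always means "more of the event" (`sign = -1` for a
#' loss flips the score).
#'
#' @param scores a [score_matrix()] with >= 3 samples.
#' @param bands1,bands2 character vectors of cytoband names.
#' @param sign1,sign2 `+1` for a gain event, `-1` for a loss event.
#' @return List with `r` (Pearson correlation), `p_value` (two-sided,
#'   t-based), `n`.
#' @export
correlate_events <- function(scores, bands1, bands2, sign1 = 1, sign2 = 1) {
  if (nrow(scores) < 3L) stop("event correlation needs >= 3 samples")
  for (bs in list(bands1, bands2)) {
    missing <- setdiff(bs, colnames(scores))
    if (length(missing)) stop("unknown cytoband '", missing[1L], "'")
  }
  i1 <- sign1 * rowMeans(scores[, bands1, drop = FALSE])
  i2 <- sign2 * rowMeans(scores[, bands2, drop = FALSE])
  if (stats::sd(i1) == 0 || stats::sd(i2) == 0) {
    stop("event intensity has zero variance")
  }
  ct <- stats::cor.test(i1, i2, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(scores))
}

#' Group samples by tumor size
#'
#' Thin annotation filter splitting tumors into the small (< `low` cm),
#' medium, and large (> `high` cm) groups used for size-stratified
#' comparisons.
#'
#' @param annotations a [sample_annotations()] data.frame with `size_cm`.
#' @param low,high size cut points in cm (defaults 3 and 7).
#' @return Named list of sample-id vectors: `small`, `medium`, `large`
#'   (samples with unknown size are omitted).
#' @export
size_groups <- function(annotations, low = 3, high = 7) {
  sz <- annotations$size_cm
  known <- !is.na(sz)
  list(
    small = annotations$sample_id[known & sz < low],
    medium = annotations$sample_id[known & sz >= low & sz <= high],
    large = annotations$sample_id[known & sz > high]
  )
}
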