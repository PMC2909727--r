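#' Tri-state cytoband calls
#'
#' Thresholds a score matrix into per-sample, per-cytoband calls: a score
#' strictly greater than `cutoff` is a gain, strictly less than `-cutoff` a
#' loss, anything else neutral.  The default cutoff of 10 is on the scale of
#' the cytoband t-scores.
#'
#' @param scores a [score_matrix()].
#' @param cutoff positive call threshold (default 10).
#' @return An object of class `call_table`: a character matrix with entries
#'   `"loss"`, `"neutral"`, `"gain"`, same dimnames as `scores`.
#' @export
call_cytobands <- function(scores, cutoff = 10) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  calls <- matrix("neutral", nrow = nrow(scores), ncol = ncol(scores),
                  dimnames = dimnames(scores))
  calls[scores > cutoff] <- "gain"
  calls[scores < -cutoff] <- "loss"
  structure(calls, class = c("call_table", "matrix", "array"))
}

#' Per-cytoband loss/gain proportions across a sample group
#'
#' @param calls a `call_table` (all samples, or subset rows first).
#' @return data.frame with `band`, `loss_prop`, `gain_prop` in the call
#'   table's column order (genome order).
#' @export
call_proportions <- function(calls) {
  n <- nrow(calls)
  if (n < 1L) stop("call table has no samples")
  data.frame(
    band = colnames(calls),
    loss_prop = colMeans(calls == "loss"),
    gain_prop = colMeans(calls == "gain"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Arm-level loss/gain summary
#'
#' An arm's loss (gain) proportion is the highest loss (gain) proportion
#' among its cytobands; the arm is an overall loss if the loss proportion
#' exceeds the gain proportion, an overall gain in the opposite case, and
#' undecided on an exact tie.
#'
#' @param calls a `call_table`.
#' @param genome the `genome_map` the calls derive from (cytobands absent
#'   from the call table -- e.g. merged away -- are ignored).
#' @param arm arm identifier such as `"3p"`.
#' @return List with `arm`, `loss_prop`, `gain_prop`, `overall` (one of
#'   `"loss"`, `"gain"`, `"undecided"`), `n_loss`, `n_gain` (event counts at
#'   the proportion-maximizing band), and `n` (samples).
#' @export
arm_summary <- function(calls, genome, arm) {
  bands <- genome$bands$name[region_bands(genome, arm)]
  bands <- intersect(bands, colnames(calls))
  if (!length(bands)) stop("arm '", arm, "' has no cytobands in the call table")
  sub <- calls[, bands, drop = FALSE]
  loss_p <- colMeans(sub == "loss")
  gain_p <- colMeans(sub == "gain")
  loss_prop <- max(loss_p)
  gain_prop <- max(gain_p)
  list(
    arm = arm,
    loss_prop = loss_prop,
    gain_prop = gain_prop,
    overall = if (loss_prop > gain_prop) "loss"
              else if (gain_prop > loss_prop) "gain" else "undecided",
    n_loss = as.integer(round(loss_prop * nrow(sub))),
    n_gain = as.integer(round(gain_prop * nrow(sub))),
    n = nrow(sub)
  )
}

#' Arm-level summary for every arm
#'
#' @inheritParams arm_summary
#' @return data.frame with one row per arm in genome order.
#' @export
arm_summary_all <- function(calls, genome) {
  arms <- arm_names(genome)
  rows <- lapply(arms, function(a) as.data.frame(arm_summary(calls, genome, a),
                                                 stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Read a study event-count table
#'
#' Reads the packaged (or a user-supplied) TSV of published per-study event
#' counts: columns `study`, `event` (e.g. `"-3p"`, `"+5q"`), `stage`
#' (`S1`..`S4` or `all`), `events`, `total`.
#'
#' @param path TSV path; default is the packaged table of six ccRCC studies.
#' @return data.frame of counts.
#' @export
read_study_counts <- function(path = system.file("extdata", "study_event_counts.tsv",
                                                 package = "cnascan")) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  req <- c("study", "event", "stage", "events", "total")
  if (!all(req %in% names(tab))) {
    stop("study count table must have columns: ", paste(req, collapse = ", "))
  }
  if (any(tab$total <= 0L)) stop("study totals must be positive")
  if (any(tab$events < 0L | tab$events > tab$total)) {
    stop("event counts must lie in [0, total]")
  }
  tab
}

#' Pool event counts across studies
#'
#' Fixed pooling of published counts: sums events and totals over the
#' selected studies and reports the percentage rounded to the nearest
#' integer (half away from zero).
#'
#' @param counts data.frame as returned by [read_study_counts()].
#' @param event event label to pool (e.g. `"-3p"`).
#' @param stage stage stratum `"S1"`..`"S4"`, or `"all"` for the per-study
#'   overall rows.
#' @return List with `events`, `total`, `percent` (integer), and
#'   `n_studies`.
#' @export
pool_counts <- function(counts, event, stage = "all") {
  sel <- counts[counts$event == event & counts$stage == stage, , drop = FALSE]
  if (!nrow(sel)) {
    stop("no study rows for event '", event, "' at stage '", stage, "'")
  }
  ev <- sum(sel$events)
  tot <- sum(sel$total)
  list(events = ev, total = tot,
       percent = round_half_away(100 * ev / tot),
       n_studies = nrow(sel))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read the study size table
#'
#' Per-study cohort sizes and detection platforms for the packaged
#' cross-study comparison (columns `study`, `method`, `n_samples`).
#'
#' @param path TSV path; defaults to the packaged table.
#' @return data.frame.
#' @export
read_study_sizes <- function(path = system.file("extdata", "study_sizes.tsv",
                                                package = "cnascan")) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
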