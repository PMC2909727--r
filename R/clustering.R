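#' Unsupervised clustering of samples on cytoband scores
#'
#' Agglomerative hierarchical clustering of the score-matrix rows.  The
#' default distance is the correlation distance (`1 - r` between sample
#' score profiles) with Ward linkage: alteration scores scale with tumor
#' purity and event breadth, and the correlation distance groups samples by
#' the *pattern* of altered bands rather than by overall score magnitude.
#' Euclidean distance and average or complete linkage are available.  The
#' procedure is deterministic for fixed inputs.
#'
#' @param scores a [score_matrix()].
#' @param k number of flat clusters to cut (`k <= n` samples).
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"ward"`, `"average"` or `"complete"`.
#' @return List of class `cluster_result` with `tree` (an `hclust`),
#'   `labels` (named integer cluster per sample), `k`, `distance`,
#'   `linkage`.
#' @export
cluster_samples <- function(scores, k, distance = c("correlation", "euclidean"),
                            linkage = c("ward", "average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  n <- nrow(scores)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")")
  if (k < 1L) stop("k must be >= 1")
  d <- switch(distance,
    euclidean = stats::dist(unclass(scores)),
    correlation = stats::as.dist(1 - stats::cor(t(unclass(scores))))
  )
  method <- switch(linkage, ward = "ward.D2", average = "average",
                   complete = "complete")
  tree <- stats::hclust(d, method = method)
  labels <- stats::cutree(tree, k = k)
  structure(list(tree = tree, labels = labels, k = k,
                 distance = distance, linkage = linkage),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result: ", length(x$labels), " samples, k = ", x$k, " (",
      x$distance, " distance, ", x$linkage, " linkage)\n", sep = "")
  invisible(x)
}

#' Subtype-recovery accuracy under optimal label matching
#'
#' Accuracy of cluster labels against true classes under the best
#' one-to-one mapping of clusters to classes (solved exactly as an
#' assignment problem).  Clusters left unmatched -- possible when there are
#' more clusters than classes -- count all their members as errors.  The
#' result is invariant to any relabeling of clusters or classes.
#'
#' @param labels cluster labels (any atomic type).
#' @param truth true class labels, same length.
#' @return Accuracy in \[0, 1\]: the matched fraction of samples.
#' @export
mapped_accuracy <- function(labels, truth) {
  if (length(labels) != length(truth)) stop("labels and truth differ in length")
  if (!length(labels)) stop("empty label vectors")
  lab <- as.integer(factor(labels))
  tru <- as.integer(factor(truth))
  counts <- table(lab, tru)
  agree <- matrix(as.numeric(counts), nrow = nrow(counts))
  # maximize matches == minimize (max - agree) as an assignment cost
  k <- max(dim(agree))
  cost <- matrix(max(agree), k, k)
  cost[seq_len(nrow(agree)), seq_len(ncol(agree))] <- max(agree) - agree
  match_cols <- solve_assignment(cost)
  matched <- 0
  for (i in seq_len(nrow(agree))) {
    j <- match_cols[i]
    if (j <= ncol(agree)) matched <- matched + agree[i, j]
  }
  matched / length(labels)
}

# Exact square assignment problem (Hungarian algorithm with potentials,
# O(n^3)); returns, for each row, the assigned column minimizing total cost.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)       # row potentials (index r+1; r=0 virtual)
  v <- numeric(n + 1L)       # column potentials (index c+1; c=0 virtual)
  p <- integer(n + 1L)       # p[c+1]: row assigned to column c (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

#' Export a cluster tree as Newick
#'
#' Writes the linkage tree with merge heights as branch lengths, so it can
#' be inspected with standard phylogenetics tooling.
#'
#' @param result a `cluster_result` from [cluster_samples()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_newick <- function(result, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  phy <- ape::as.phylo(result$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Rank-based AUC of a score for a binary condition
#'
#' Area under the ROC curve of `score` for separating `positive` from
#' negative samples, computed from rank sums (the Wilcoxon statistic); ties
#' get half credit.  Used to quantify how well a band's alteration score
#' separates event carriers from non-carriers.
#'
#' @param score numeric scores.
#' @param positive logical, same length.
#' @return AUC in \[0, 1\].
#' @export
score_auc <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both positive and negative samples")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
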