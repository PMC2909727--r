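#' SNP copy-number profile
#'
#' One sample's per-SNP log2 copy-number ratios (0 = diploid), aligned
#' index-for-index with the SNP loci of a [genome_map()].
#'
#' @param sample_id sample identifier.
#' @param values numeric vector of finite log2 ratios.
#' @param genome optional `genome_map`; if given, the length is validated
#'   against its SNP count.
#' @return An object of class `snp_profile`.
#' @export
snp_profile <- function(sample_id, values, genome = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  values <- as.numeric(values)
  if (!all(is.finite(values))) stop("profile '", sample_id, "' has non-finite values")
  if (!is.null(genome) && length(values) != n_snps(genome)) {
    stop("profile '", sample_id, "' has ", length(values),
         " values but the genome map has ", n_snps(genome), " SNP loci")
  }
  structure(list(sample_id = sample_id, values = values), class = "snp_profile")
}

#' @export
print.snp_profile <- function(x, ...) {
  cat("snp_profile '", x$sample_id, "': ", length(x$values), " SNPs\n", sep = "")
  invisible(x)
}

#' Read a SNP profile matrix
#'
#' Reads a tab-separated matrix with columns `snp_id`, `chrom`, `pos`, then
#' one column per sample.  Rows are normalized to genome order; every
#' position must fall inside a cytoband of `genome` and every cell must be
#' present (no imputation is performed).
#'
#' @param path TSV path.
#' @param genome a `genome_map` (with or without SNP loci; loci are rebuilt
#'   from the file and validated against the band map).
#' @return List with `genome` (loci attached) and `profiles` (list of
#'   [snp_profile()] in column order).
#' @export
read_profile_matrix <- function(path, genome) {
  stopifnot(inherits(genome, "genome_map"))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA)
  if (ncol(tab) < 4L) stop("profile matrix needs snp_id, chrom, pos and >= 1 sample column")
  names(tab)[1:3] <- c("snp_id", "chrom", "pos")
  genome <- set_snp_loci(genome, data.frame(
    chrom = tab$chrom, pos = tab$pos, id = tab$snp_id, stringsAsFactors = FALSE
  ))
  ord <- match(genome$snps$id, tab$snp_id)
  sample_ids <- names(tab)[-(1:3)]
  profiles <- lapply(sample_ids, function(sid) {
    v <- tab[[sid]][ord]
    if (anyNA(v)) {
      miss <- genome$snps$id[which(is.na(v))[1L]]
      stop("missing value for SNP '", miss, "' in sample '", sid, "'")
    }
    snp_profile(sid, v, genome)
  })
  list(genome = genome, profiles = profiles)
}

#' Write a SNP profile matrix
#'
#' Inverse of [read_profile_matrix()]; rows in genome order, full float
#' precision.  Also used for smoothed profiles (same dialect).
#'
#' @param profiles list of [snp_profile()] (or smoothed profiles).
#' @param genome the bound `genome_map` (must carry SNP loci).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(profiles, genome, path) {
  stopifnot(inherits(genome, "genome_map"), n_snps(genome) > 0L)
  out <- data.frame(snp_id = genome$snps$id, chrom = genome$snps$chrom,
                    pos = genome$snps$pos, stringsAsFactors = FALSE)
  for (p in profiles) {
    if (length(p$values) != n_snps(genome)) {
      stop("profile '", p$sample_id, "' is not aligned to the genome map")
    }
    out[[p$sample_id]] <- formatC(p$values, format = "g", digits = 17)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cytoband alteration score matrix
#'
#' Samples x cytobands signed alteration scores: positive = gain, negative =
#' loss.  Columns are in genome order.
#'
#' @param scores numeric matrix, rownames = sample ids, colnames = cytoband
#'   names.
#' @param method the regional test that produced the scores ("t" or
#'   "binomial").
#' @return An object of class `score_matrix` (a matrix with a `method`
#'   attribute).
#' @export
score_matrix <- function(scores, method = "t") {
  stopifnot(is.matrix(scores), is.numeric(scores))
  if ((is.null(rownames(scores)) && nrow(scores) > 0L) ||
      is.null(colnames(scores))) {
    stop("score matrix needs sample rownames and cytoband colnames")
  }
  if (anyDuplicated(colnames(scores))) stop("duplicate cytoband names in score matrix")
  if (nrow(scores) > 0L && !all(is.finite(scores))) {
    stop("score matrix has non-finite entries")
  }
  structure(scores, method = method, class = c("score_matrix", class(scores)))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix: ", nrow(x), " samples x ", ncol(x), " cytobands (method ",
      attr(x, "method"), ")\n", sep = "")
  invisible(x)
}

#' Write a score matrix to TSV
#'
#' Lossless round-trip: samples as rows, cytobands as columns, full float
#' precision; `read_score_matrix(write_score_matrix(x))` reproduces `x`.
#'
#' @param scores a [score_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(scores, path) {
  if (anyDuplicated(colnames(scores))) stop("duplicate cytoband names")
  if (nrow(scores) > 0L && any(is.nan(scores))) stop("NaN score cannot be written")
  rn <- rownames(scores)
  if (is.null(rn)) rn <- character(0)
  txt <- matrix(formatC(scores, format = "g", digits = 17),
                nrow = nrow(scores), ncol = ncol(scores),
                dimnames = list(rn, colnames(scores)))
  out <- cbind(data.frame(sample_id = rn, stringsAsFactors = FALSE),
               as.data.frame(txt, stringsAsFactors = FALSE, optional = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score matrix from TSV
#' @param path TSV written by [write_score_matrix()].
#' @param method method tag to attach (default "t").
#' @return A [score_matrix()].
#' @export
read_score_matrix <- function(path, method = "t") {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  cols <- header[-1L]
  if (anyDuplicated(cols)) stop("duplicate cytoband names in score matrix file")
  m <- matrix(numeric(0), nrow = nrow(tab), ncol = length(cols),
              dimnames = list(tab[[1L]], cols))
  if (nrow(tab) > 0L) {
    m[] <- as.matrix(tab[, -1L, drop = FALSE])
  }
  score_matrix(m, method = method)
}

#' Validate a sample annotation table
#'
#' Annotations carry the clinicopathological covariates used to group
#' samples: RCC subtype, TNM stage, Fuhrman grade, tumor size and tri-state
#' clinical flags.  Unknowns are explicit (`"unknown"`), never empty strings.
#'
#' @param ann data.frame with columns `sample_id`, `subtype` (CC, PA, CH,
#'   ON), `stage` (S1a, S1b, S2, S3a, S3b4, unknown), `grade` (1..4 in half
#'   steps, or "unknown"), `size_cm` (positive or NA), plus optional
#'   tri-state flag columns (yes/no/unknown).
#' @return The validated data.frame, invisibly classed `sample_annotations`.
#' @export
sample_annotations <- function(ann) {
  stopifnot(is.data.frame(ann))
  req <- c("sample_id", "subtype", "stage", "grade")
  if (!all(req %in% names(ann))) {
    stop("annotations must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(ann$subtype %in% c("CC", "PA", "CH", "ON"))) stop("invalid subtype")
  if (!all(ann$stage %in% c("S1a", "S1b", "S2", "S3a", "S3b4", "unknown"))) {
    stop("invalid stage")
  }
  grade_ok <- ann$grade %in% c(as.character(seq(1, 4, by = 0.5)), "unknown")
  if (!all(grade_ok)) stop("invalid grade")
  if (anyDuplicated(ann$sample_id)) stop("duplicate sample_id")
  class(ann) <- unique(c("sample_annotations", class(ann)))
  invisible(ann)
}
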