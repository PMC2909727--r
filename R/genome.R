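#' Genome coordinate map
#'
#' A `genome_map` is the coordinate backbone shared by every pipeline stage:
#' an ordered set of autosomes ("1".."22"), each tiled by non-overlapping
#' cytobands assigned to the p or q arm, plus (optionally) the SNP loci of
#' the array, each mapped to exactly one cytoband.  Analysis is restricted to
#' autosomes; chromosome X and Y are never represented.
#'
#' All coordinates are 0-based half-open internally (the UCSC cytoBand.txt
#' convention).  Genome order -- chromosome 1 to 22, p arm before q arm,
#' bands by start position -- is a total order, and every function that emits
#' per-cytoband output emits it in this order.
#'
#' @param bands data.frame with columns `chrom` (character, "1".."22"),
#'   `start`, `end` (0-based half-open base pairs), `name` (e.g. "3p25"),
#'   `arm` ("p" or "q").
#' @param snps optional data.frame with columns `chrom`, `pos`, `id` giving
#'   the array's SNP loci.
#' @return An object of class `genome_map` with elements `bands` (with bands
#'   in genome order) and `snps` (genome-ordered, with a `band` column
#'   holding the row index of the containing cytoband; `NULL` if no loci
#'   were supplied).
#' @export
genome_map <- function(bands, snps = NULL) {
  stopifnot(is.data.frame(bands))
  req <- c("chrom", "start", "end", "name", "arm")
  if (!all(req %in% names(bands))) {
    stop("bands must have columns: ", paste(req, collapse = ", "))
  }
  bands$chrom <- as.character(bands$chrom)
  if (any(bands$chrom %in% c("X", "Y", "chrX", "chrY"))) {
    stop("chromosome X/Y bands are not allowed in a genome_map")
  }
  chrom_num <- suppressWarnings(as.integer(bands$chrom))
  if (anyNA(chrom_num) || any(chrom_num < 1L) || any(chrom_num > 22L)) {
    stop("chromosomes must be autosomes \"1\"..\"22\"")
  }
  if (!all(bands$arm %in% c("p", "q"))) stop("arm must be \"p\" or \"q\"")
  if (any(bands$end <= bands$start)) {
    bad <- which(bands$end <= bands$start)[1L]
    stop("cytoband '", bands$name[bad], "' has end <= start")
  }
  ord <- order(chrom_num, bands$start)
  bands <- bands[ord, , drop = FALSE]
  chrom_num <- chrom_num[ord]
  # per-chromosome tiling: starts at 0, contiguous, p entirely before q
  for (ch in unique(bands$chrom)) {
    b <- bands[bands$chrom == ch, , drop = FALSE]
    if (b$start[1L] != 0) {
      stop("chromosome ", ch, " bands do not start at 0 ('", b$name[1L], "')")
    }
    if (nrow(b) > 1L) {
      gap <- which(b$start[-1L] != b$end[-nrow(b)])
      if (length(gap)) {
        stop("cytobands overlap or leave a gap on chromosome ", ch,
             " at band '", b$name[gap[1L] + 1L], "'")
      }
    }
    if (is.unsorted(match(b$arm, c("p", "q")))) {
      stop("on chromosome ", ch, " a q band precedes a p band")
    }
  }
  if (anyDuplicated(bands$name)) {
    stop("duplicate cytoband name '", bands$name[duplicated(bands$name)][1L], "'")
  }
  rownames(bands) <- NULL
  g <- structure(list(bands = bands, snps = NULL), class = "genome_map")
  if (!is.null(snps)) g <- set_snp_loci(g, snps)
  g
}

#' Attach SNP loci to a genome map
#'
#' Sorts the loci into genome order and maps each to its containing cytoband.
#'
#' @param genome a `genome_map`.
#' @param snps data.frame with columns `chrom`, `pos` (0-based), `id`.
#' @return The genome map with `$snps` populated (columns `chrom`, `pos`,
#'   `id`, `band`).
#' @export
set_snp_loci <- function(genome, snps) {
  stopifnot(inherits(genome, "genome_map"), is.data.frame(snps))
  if (!all(c("chrom", "pos", "id") %in% names(snps))) {
    stop("snps must have columns chrom, pos, id")
  }
  snps$chrom <- sub("^chr", "", as.character(snps$chrom))
  cn <- suppressWarnings(as.integer(snps$chrom))
  if (anyNA(cn)) {
    bad <- snps$chrom[which(is.na(cn))[1L]]
    stop("SNP on unsupported chromosome '", bad, "'")
  }
  ord <- order(cn, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  bands <- genome$bands
  band_idx <- integer(nrow(snps))
  for (ch in unique(snps$chrom)) {
    bi <- which(bands$chrom == ch)
    si <- which(snps$chrom == ch)
    if (!length(bi)) stop("SNPs on chromosome ", ch, " absent from the genome map")
    k <- findInterval(snps$pos[si], bands$start[bi])
    out <- k < 1L | snps$pos[si] >= bands$end[bi][pmax(k, 1L)]
    if (any(out)) {
      stop("SNP '", snps$id[si][which(out)[1L]],
           "' at ", ch, ":", snps$pos[si][which(out)[1L]],
           " falls outside every cytoband")
    }
    band_idx[si] <- bi[k]
  }
  snps$band <- band_idx
  rownames(snps) <- NULL
  genome$snps <- snps
  genome
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", length(unique(x$bands$chrom)), "chromosomes,",
      nrow(x$bands), "cytobands,",
      if (is.null(x$snps)) 0L else nrow(x$snps), "SNP loci\n")
  invisible(x)
}

#' Number of SNP loci in a genome map
#' @param genome a `genome_map`.
#' @return Integer count.
#' @export
n_snps <- function(genome) {
  if (is.null(genome$snps)) 0L else nrow(genome$snps)
}

#' Cytoband names in genome order
#' @param genome a `genome_map`.
#' @return Character vector.
#' @export
band_names <- function(genome) genome$bands$name

#' Chromosome-arm identifiers in genome order
#' @param genome a `genome_map`.
#' @return Character vector such as `c("1p", "1q", ...)`, each arm once.
#' @export
arm_names <- function(genome) {
  unique(paste0(genome$bands$chrom, genome$bands$arm))
}

#' Resolve a genomic region to SNP indices
#'
#' Regions name a whole chromosome (`"7"`), a chromosome arm (`"3p"`), a
#' single cytoband (`"5q3"`), or an inclusive band range on one arm
#' (`"5q2:5q4"`).
#'
#' @param genome a `genome_map` with SNP loci attached.
#' @param region region string.
#' @return Integer vector of SNP indices (rows of `genome$snps`).
#' @export
region_snps <- function(genome, region) {
  idx <- region_bands(genome, region)
  which(genome$snps$band %in% idx)
}

#' Resolve a genomic region to cytoband row indices
#' @inheritParams region_snps
#' @return Integer vector of rows of `genome$bands`.
#' @export
region_bands <- function(genome, region) {
  b <- genome$bands
  if (grepl(":", region, fixed = TRUE)) {
    ends <- strsplit(region, ":", fixed = TRUE)[[1L]]
    i1 <- match(ends[1L], b$name)
    i2 <- match(ends[2L], b$name)
    if (is.na(i1) || is.na(i2)) stop("unknown cytoband in region '", region, "'")
    return(seq(min(i1, i2), max(i1, i2)))
  }
  if (grepl("^[0-9]+$", region)) {
    idx <- which(b$chrom == region)
    if (!length(idx)) stop("unknown chromosome '", region, "'")
    return(idx)
  }
  if (grepl("^[0-9]+[pq]$", region)) {
    ch <- sub("[pq]$", "", region)
    arm <- substring(region, nchar(region))
    idx <- which(b$chrom == ch & b$arm == arm)
    if (!length(idx)) stop("unknown arm '", region, "'")
    return(idx)
  }
  idx <- match(region, b$name)
  if (is.na(idx)) stop("unknown region '", region, "'")
  idx
}

#' Build a synthetic genome map
#'
#' Constructs a compact 22-autosome map with a fixed number of cytobands per
#' arm and equally spaced SNP loci per band.  Useful as the backbone for
#' simulated cohorts; real analyses use [read_cytoband_file()].
#'
#' @param bands_per_arm cytobands per arm (default 3).
#' @param snps_per_band SNP loci per cytoband (default 60; with 22
#'   autosomes and 3 bands per arm this is a ~8000-SNP array, a 1/12-scale
#'   stand-in for a 100K chip with its typical per-band probe density).
#' @param band_bp width of each cytoband in base pairs (default 1e7).
#' @return A `genome_map` with SNP loci attached.
#' @export
make_genome <- function(bands_per_arm = 3L, snps_per_band = 60L, band_bp = 1e7) {
  stopifnot(bands_per_arm >= 1L, snps_per_band >= 1L, band_bp > 0)
  rows <- list()
  for (ch in 1:22) {
    k <- 0L
    for (arm in c("p", "q")) {
      for (i in seq_len(bands_per_arm)) {
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = as.character(ch),
          start = k * band_bp,
          end = (k + 1L) * band_bp,
          name = paste0(ch, arm, i),
          arm = arm,
          stringsAsFactors = FALSE
        )
        k <- k + 1L
      }
    }
  }
  bands <- do.call(rbind, rows)
  step <- band_bp / (snps_per_band + 1L)
  snps <- do.call(rbind, lapply(seq_len(nrow(bands)), function(j) {
    data.frame(
      chrom = bands$chrom[j],
      pos = round(bands$start[j] + step * seq_len(snps_per_band)),
      stringsAsFactors = FALSE
    )
  }))
  snps$id <- sprintf("SNP_%05d", seq_len(nrow(snps)))
  genome_map(bands, snps)
}

#' Read a UCSC cytoBand.txt file
#'
#' Parses the tab-separated UCSC cytoBand dialect (chrom, start, end, band
#' name, optional Giemsa stain; 0-based half-open coordinates) into a
#' [genome_map()].  Band names are rewritten to the "3p25" style without the
#' "chr" prefix, the arm is taken from the band name's leading letter, and
#' chrX/chrY rows are dropped with a warning.  Sub-bands (e.g. p25.1) are
#' kept as given; no merging to major bands is performed.
#'
#' @param path path to a cytoBand.txt-style file (no header).
#' @return A `genome_map` without SNP loci.
#' @export
read_cytoband_file <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(raw) < 4L) stop("cytoband file needs >= 4 tab-separated columns")
  names(raw)[1:4] <- c("chrom", "start", "end", "band")
  chrom <- sub("^chr", "", raw$chrom)
  sex <- chrom %in% c("X", "Y")
  if (any(sex)) {
    warning("dropping ", sum(sex), " chrX/chrY cytoband rows (autosomes only)")
    raw <- raw[!sex, , drop = FALSE]
    chrom <- chrom[!sex]
  }
  if (!nrow(raw)) stop("cytoband file holds no autosome rows")
  arm <- substr(raw$band, 1L, 1L)
  if (!all(arm %in% c("p", "q"))) {
    bad <- which(!arm %in% c("p", "q"))[1L]
    stop("band name '", raw$band[bad], "' (line ", rownames(raw)[bad],
         ") does not start with p or q")
  }
  bad_span <- which(raw$end <= raw$start)
  if (length(bad_span)) {
    stop("cytoband line ", rownames(raw)[bad_span[1L]],
         " ('", raw$band[bad_span[1L]], "') has end <= start")
  }
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    disorder <- which(diff(raw$start[i]) <= 0)
    if (length(disorder)) {
      stop("cytoband line ", rownames(raw)[i[disorder[1L] + 1L]],
           " ('", raw$band[i[disorder[1L] + 1L]],
           "') is out of order or overlaps on chromosome ", ch)
    }
  }
  bands <- data.frame(
    chrom = chrom,
    start = raw$start,
    end = raw$end,
    name = paste0(chrom, raw$band),
    arm = arm,
    stringsAsFactors = FALSE
  )
  genome_map(bands)
}
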