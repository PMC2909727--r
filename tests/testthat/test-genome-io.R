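test_that("cytoband files parse into a validated genome map", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "chr1\t0\t5000000\tp36\tgneg",
    "chr1\t5000000\t9000000\tp35\tgpos50"
  ), path)
  g <- read_cytoband_file(path)
  expect_s3_class(g, "genome_map")
  expect_equal(nrow(g$bands), 2L)
  expect_equal(g$bands$name, c("1p36", "1p35"))
  expect_equal(g$bands$arm, c("p", "p"))
})

test_that("chrX rows are dropped with a warning and never reach the map", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "chr2\t0\t1000\tp1\tgneg",
    "chr2\t1000\t2000\tq1\tgneg",
    "chrX\t0\t900\tp22\tgneg"
  ), path)
  expect_warning(g <- read_cytoband_file(path), "chrX/chrY")
  expect_false(any(g$bands$chrom == "X"))
  expect_equal(nrow(g$bands), 2L)
})

test_that("malformed cytoband files are rejected with the offending band named", {
  bad_span <- withr::local_tempfile(fileext = ".txt")
  writeLines("chr1\t500\t100\tp36\tgneg", bad_span)
  expect_error(read_cytoband_file(bad_span), "p36")

  disorder <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "chr1\t1000\t2000\tp35\tgneg",
    "chr1\t0\t1000\tp36\tgneg"
  ), disorder)
  expect_error(read_cytoband_file(disorder), "out of order|overlap")

  overlap <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "chr1\t0\t1500\tp36\tgneg",
    "chr1\t1000\t2000\tp35\tgneg"
  ), overlap)
  expect_error(read_cytoband_file(overlap))
})

test_that("profile matrices read back aligned to genome order", {
  g <- genome_map(data.frame(
    chrom = "1", start = c(0, 500), end = c(500, 1000),
    name = c("1p1", "1q1"), arm = c("p", "q")
  ))
  tab <- data.frame(
    snp_id = sprintf("s%02d", 1:10), chrom = "1",
    pos = seq(50, 950, by = 100),
    A = rnorm(10), B = rnorm(10)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  res <- read_profile_matrix(path, g)
  expect_length(res$profiles, 2L)
  expect_equal(vapply(res$profiles, `[[`, "", "sample_id"), c("A", "B"))
  expect_length(res$profiles[[1]]$values, 10L)

  # unsorted rows normalize to the same result
  shuffled <- tab[sample(10), ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(shuffled, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  res2 <- read_profile_matrix(path2, g)
  expect_identical(res$profiles[[1]]$values, res2$profiles[[1]]$values)
  expect_identical(res$profiles[[2]]$values, res2$profiles[[2]]$values)
})

test_that("profile matrix readers reject missing cells and stray positions", {
  g <- genome_map(data.frame(
    chrom = "1", start = 0, end = 1000, name = "1p1", arm = "p"
  ))
  tab <- data.frame(snp_id = c("s1", "s2", "s3", "s4"), chrom = "1",
                    pos = c(10, 20, 30, 40), A = c(0.1, NA, 0.3, 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profile_matrix(path, g), "s2.*A|A.*s2")

  tab$A <- 0.1
  tab$pos[4] <- 5000   # outside every band
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_profile_matrix(path, g), "outside")
})

test_that("score matrices round-trip losslessly through TSV", {
  m <- matrix(c(pi, -exp(1), 1 / 3, 0.1234567890123456, -1e-17, 42),
              nrow = 2, dimnames = list(c("sA", "sB"), c("1p1", "1q1", "2p1")))
  sm <- score_matrix(m)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(sm, path)
  back <- read_score_matrix(path)
  expect_equal(unclass(back)[, ], unclass(sm)[, ], tolerance = 0)

  # empty sample set: header-only file, read back empty
  empty <- score_matrix(matrix(numeric(0), nrow = 0, ncol = 2,
                               dimnames = list(NULL, c("1p1", "1q1"))))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(empty, path2)
  back2 <- read_score_matrix(path2)
  expect_equal(nrow(back2), 0L)
  expect_equal(colnames(back2), c("1p1", "1q1"))

  # NaN refuses to serialize
  m[1, 1] <- NaN
  expect_error(write_score_matrix(m, path), "NaN")
})

test_that("genome order is total: chrom 1..22, p before q, bands by start", {
  g <- make_genome(bands_per_arm = 2L, snps_per_band = 5L)
  b <- g$bands
  chrom_num <- as.integer(b$chrom)
  arm_rank <- match(b$arm, c("p", "q"))
  key <- order(chrom_num, arm_rank, b$start)
  expect_identical(key, seq_len(nrow(b)))
  expect_false(is.unsorted(order(chrom_num)))
  # every SNP maps to exactly one band, every band to one arm
  expect_true(all(g$snps$band >= 1 & g$snps$band <= nrow(b)))
  expect_true(all(table(paste(b$name)) == 1))
})

test_that("region resolution covers chromosome, arm, band and range forms", {
  g <- make_genome(bands_per_arm = 3L, snps_per_band = 4L)
  expect_length(region_bands(g, "7"), 6L)
  expect_length(region_bands(g, "3p"), 3L)
  expect_length(region_bands(g, "5q2"), 1L)
  expect_length(region_bands(g, "5q1:5q3"), 3L)
  expect_error(region_bands(g, "23"), "unknown")
  expect_equal(length(region_snps(g, "3p")), 12L)
})
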