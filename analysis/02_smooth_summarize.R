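#!/usr/bin/env Rscript
# Denoise the raw per-SNP log2 ratios with moving-window t smoothing
# (window 31 SNPs) and summarize each sample into signed cytoband
# alteration scores.  Scores are written under results/.

suppressPackageStartupMessages(library(cnascan))

genome <- make_genome()

for (cohort in c("stage", "survival", "subtype")) {
  infile <- sprintf("results/sim/%s_profiles.tsv", cohort)
  res <- read_profile_matrix(infile, genome)
  smoothed <- smooth_cohort(res$profiles, res$genome, window_snps = 31L)
  scores <- summarize_cytobands(smoothed, res$genome, method = "t")
  out <- sprintf("results/%s_scores.tsv", cohort)
  write_score_matrix(scores, out)
  cat(sprintf("%s cohort: %d samples x %d cytobands -> %s\n",
              cohort, nrow(scores), ncol(scores), out))
  cat(sprintf("  score range %.1f .. %.1f; cross-sample IQR > 2.5 for %d bands\n",
              min(scores), max(scores),
              sum(vapply(colnames(scores),
                         function(b) score_iqr(scores, b), 0) > 2.5)))
}
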