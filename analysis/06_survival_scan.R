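#!/usr/bin/env Rscript
# Resampled per-cytoband survival scan on the 200-tumor survival cohort:
# bands with cross-sample score IQR > 2.5 are tested for association with
# disease-specific survival by averaging Cox score-test -log10(p) and
# coefficients over 100 random 80% patient subsets, then compared with a
# permutation null.

suppressPackageStartupMessages(library(cnascan))

scores <- read_score_matrix("results/survival_scores.tsv")
surv <- read.table("results/sim/survival_records.tsv", sep = "\t",
                   header = TRUE, stringsAsFactors = FALSE)

scan <- resampled_scan(scores, surv, iqr_min = 2.5, n_models = 100L,
                       subset_fraction = 0.8, seed = 20260923)
write.table(scan, "results/survival_scan.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

inc <- scan[scan$included, ]
cat(sprintf("%d of %d bands passed the IQR filter\n", nrow(inc), nrow(scan)))
top <- inc[order(-inc$mean_neglog10_p), ][1:5, ]
cat("strongest survival associations:\n")
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-5s mean -log10(p) = %.2f, mean coef = %+.4f (%d models)\n",
              top$band[i], top$mean_neglog10_p[i], top$mean_coefficient[i],
              top$n_models_used[i]))
}

set.seed(20260924)
perm <- surv
perm$sample_id <- sample(perm$sample_id)
scan0 <- resampled_scan(scores, perm, iqr_min = 2.5, n_models = 100L,
                        subset_fraction = 0.8, seed = 20260923)
inc0 <- scan0[scan0$included, ]
cat(sprintf("\npermutation null: max mean -log10(p) = %.2f, mean across bands = %.3f\n",
            max(inc0$mean_neglog10_p), mean(inc0$mean_neglog10_p)))
cat(sprintf("(survival was linked to +5q carriers at log hazard ratio 0.5)\n"))
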