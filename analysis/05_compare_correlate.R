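#!/usr/bin/env Rscript
# Group-level summaries of the stage cohort: per-stage box summaries of the
# cytoband scores, a studentized (Welch) comparison between the stage
# groups, and the correlation between 3p-loss and 5q-gain intensity.

suppressPackageStartupMessages(library(cnascan))

genome <- make_genome()
scores <- read_score_matrix("results/stage_scores.tsv")
ann <- read.table("results/sim/stage_annotations.tsv", sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE)

groups <- split(ann$sample_id, ann$stage)

boxes <- do.call(rbind, lapply(names(groups), function(grp) {
  group_box_summary(scores, groups[[grp]], grp)
}))
write.table(boxes, "results/stage_box_summaries.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
for (grp in names(groups)) {
  b <- boxes[boxes$group == grp, ]
  cat(sprintf("%s: %d bands majority-loss, %d majority-gain\n", grp,
              sum(b$flag == "majority_loss"), sum(b$flag == "majority_gain")))
}

cmp <- compare_groups(scores, groups[["S1a"]], groups[["S3b4"]],
                      stat_threshold = 2)
write.table(cmp, "results/stage_group_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nS1a vs S3b4: %d of %d bands significant at |t| > 2\n",
            sum(cmp$significant), nrow(cmp)))
top <- cmp[order(-abs(cmp$t)), ][1:5, c("band", "t")]
cat("strongest differences:",
    paste(sprintf("%s (t=%.1f)", top$band, top$t), collapse = ", "), "\n")

bands_3p <- band_names(genome)[region_bands(genome, "3p")]
bands_5q <- band_names(genome)[region_bands(genome, "5q")]
cr <- correlate_events(scores, bands_3p, bands_5q, sign1 = -1, sign2 = 1)
cat(sprintf("\n3p-loss vs 5q-gain intensity: Pearson r = %.2f (p = %.2f, n = %d)\n",
            cr$r, cr$p_value, cr$n))
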