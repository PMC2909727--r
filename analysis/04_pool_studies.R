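#!/usr/bin/env Rscript
# Pool the published per-study arm-event counts (six ccRCC cohorts, 572
# tumors) into combined frequencies, overall and by stage stratum.

suppressPackageStartupMessages(library(cnascan))

counts <- read_study_counts()
sizes <- read_study_sizes()
cat("combined cohorts:", nrow(sizes), "studies,", sum(sizes$n_samples),
    "ccRCC tumors\n\n")

rows <- list()
for (ev in unique(counts$event)) {
  for (st in intersect(c("all", "S1", "S2", "S3", "S4"),
                       counts$stage[counts$event == ev])) {
    p <- pool_counts(counts, ev, st)
    rows[[length(rows) + 1L]] <- data.frame(
      event = ev, stage = st, events = p$events, total = p$total,
      percent = p$percent, n_studies = p$n_studies
    )
  }
}
pooled <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(pooled, "results/pooled_event_frequencies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

overall <- pooled[pooled$stage == "all", ]
overall <- overall[order(-overall$percent), ]
cat("overall pooled frequencies:\n")
for (i in seq_len(nrow(overall))) {
  cat(sprintf("  %-5s %3d/%3d = %d%%\n", overall$event[i],
              overall$events[i], overall$total[i], overall$percent[i]))
}
cat("\nstage trend for -14q (pooled):\n")
for (st in c("S1", "S2", "S3", "S4")) {
  p <- pool_counts(counts, "-14q", st)
  cat(sprintf("  %s: %d%% (%d/%d)\n", st, p$percent, p$events, p$total))
}
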