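#!/usr/bin/env Rscript
# Build the synthetic study cohorts every later stage analyses.
#
# Three cohorts on a shared genome backbone:
#   * a stage cohort: earliest-stage (S1a) vs latest-stage (S3b4) ccRCC
#     signatures, 40 tumors each;
#   * a survival cohort: 200 ccRCC tumors with six recurrent events at
#     penetrance 0.5 and disease-specific survival linked to 5q-gain
#     carriers (log hazard ratio 0.5) -- penetrance 0.5 keeps carriers and
#     non-carriers balanced, which a survival comparison needs;
#   * a subtype cohort: CC / PA / CH / ON signatures, 10 tumors each.
# Profiles, annotations, survival and the ground-truth event table are
# written as TSV under results/sim/.

suppressPackageStartupMessages(library(cnascan))

dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)
genome <- make_genome()
cat("genome backbone:", nrow(genome$bands), "cytobands,", n_snps(genome),
    "SNP loci\n")

set.seed(20260921)
stage <- simulate_cohort(genome, stage_template_spec())
write_profile_matrix(stage$profiles, genome, "results/sim/stage_profiles.tsv")
write.table(stage$annotations, "results/sim/stage_annotations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(stage$truth, "results/sim/stage_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("stage cohort:", length(stage$profiles), "tumors;",
    sum(stage$truth$carrier), "planted events realized\n")

set.seed(20260925)
ev05 <- function(r, c) event_spec(r, c, penetrance = 0.5)
surv_spec <- cohort_spec(
  groups = list(list(
    label = "CC", subtype = "CC", stage = "unknown", n = 200L,
    events = list(ev05("3p", 1L), ev05("5q", 3L), ev05("7", 3L),
                  ev05("14", 1L), ev05("8p", 1L), ev05("1q", 3L))
  )),
  purity_range = c(0.6, 0.9), noise_sd = 0.25,
  survival = list(baseline_hazard = 1 / 1500, censor_rate = 0.3,
                  coefficients = c("+5q" = 0.5))
)
survco <- simulate_cohort(genome, surv_spec)
write_profile_matrix(survco$profiles, genome,
                     "results/sim/survival_profiles.tsv")
write.table(survco$survival, "results/sim/survival_records.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(survco$truth, "results/sim/survival_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("survival cohort:", length(survco$profiles), "tumors;",
    sum(survco$survival$event), "disease deaths;",
    sum(survco$truth$carrier[survco$truth$label == "+5q"]),
    "5q-gain carriers\n")

set.seed(20260922)
subtype <- simulate_cohort(genome, subtype_template_spec())
write_profile_matrix(subtype$profiles, genome,
                     "results/sim/subtype_profiles.tsv")
write.table(subtype$annotations, "results/sim/subtype_annotations.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(subtype$truth, "results/sim/subtype_truth.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("subtype cohort:", length(subtype$profiles), "tumors across",
    length(unique(subtype$annotations$subtype)), "subtypes\n")
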