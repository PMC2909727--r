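test_that("noiseless profiles follow the admixture closed form", {
  g <- tiny_genome()
  # purity 1, whole-arm single-copy loss: log2(1/2) = -1 on the arm, 0 off
  set.seed(1)
  p <- simulate_profile(g, list(event_spec("3p", 1L)), purity = 1,
                        noise_sd = 0)
  on_arm <- region_snps(g, "3p")
  expect_equal(unique(p$values[on_arm]), -1)
  expect_equal(unique(p$values[-on_arm]), 0)

  # purity 0.5 attenuates the loss to log2(1.5/2)
  p2 <- simulate_profile(g, list(event_spec("3p", 1L)), purity = 0.5,
                         noise_sd = 0)
  expect_equal(unique(p2$values[on_arm]), log2(1.5 / 2))
  expect_equal(log2(1.5 / 2), -0.4150375, tolerance = 1e-7)

  # no events: all zeros at any purity
  p3 <- simulate_profile(g, list(), purity = 0.7, noise_sd = 0)
  expect_equal(p3$values, rep(0, n_snps(g)))
})

test_that("mean simulated signal converges to the mixture form at several purities", {
  g <- make_genome(bands_per_arm = 1L, snps_per_band = 8L)
  idx <- region_snps(g, "5q")
  for (purity in c(0.3, 0.6, 0.9)) {
    set.seed(round(purity * 100))
    draws <- replicate(400, {
      simulate_profile(g, list(event_spec("5q", 3L)), purity,
                       noise_sd = 0.25)$values[idx[1]]
    })
    expected <- log2((purity * 3 + (1 - purity) * 2) / 2)
    # mean of 400 draws: sd 0.25/20 = 0.0125; allow 4 sigma
    expect_lt(abs(mean(draws) - expected), 0.05)
  }
})

test_that("invalid profiles are rejected", {
  g <- tiny_genome()
  expect_error(simulate_profile(g, list(), purity = 0), "purity")
  expect_error(simulate_profile(g, list(), purity = -0.5), "purity")
  expect_error(
    simulate_profile(g, list(event_spec("3p", 1L), event_spec("3", 1L)),
                     purity = 0.8),
    "overlapping"
  )
  expect_error(event_spec("3p", 2L), "diploid")
  expect_error(event_spec("3p", 1L, penetrance = 1.2), "penetrance")
})

test_that("cohorts realize penetrance, record truth, and are seed-deterministic", {
  g <- tiny_genome()
  spec <- cohort_spec(groups = list(
    list(label = "G", subtype = "CC", stage = "S1a", n = 5L,
         events = list(event_spec("3p", 1L, penetrance = 1)))
  ))
  co <- simulate_cohort_seeded(g, spec, seed = 7)
  expect_length(co$profiles, 5L)
  expect_true(all(co$truth$carrier))
  expect_equal(nrow(co$truth), 5L)

  co2 <- simulate_cohort_seeded(g, spec, seed = 7)
  expect_identical(
    lapply(co$profiles, `[[`, "values"),
    lapply(co2$profiles, `[[`, "values")
  )
  expect_identical(co$annotations$purity, co2$annotations$purity)

  # carrier fraction at penetrance 0.5 stays within 3 binomial SDs
  spec_half <- cohort_spec(groups = list(
    list(label = "H", subtype = "CC", stage = "S1a", n = 2000L,
         events = list(event_spec("6q", 1L, penetrance = 0.5)))
  ))
  g1 <- make_genome(bands_per_arm = 1L, snps_per_band = 5L)
  co3 <- simulate_cohort_seeded(g1, spec_half, seed = 11)
  frac <- mean(co3$truth$carrier)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 2000))
})

test_that("survival link draws exponential times tied to carrier status", {
  g <- make_genome(bands_per_arm = 1L, snps_per_band = 5L)
  spec <- cohort_spec(
    groups = list(list(label = "G", subtype = "CC", stage = "S1a", n = 400L,
                       events = list(event_spec("5q", 3L, penetrance = 0.5)))),
    survival = list(baseline_hazard = 1 / 1000, censor_rate = 0,
                    coefficients = c("+5q" = 1))
  )
  co <- simulate_cohort_seeded(g, spec, seed = 3)
  expect_equal(nrow(co$survival), 400L)
  expect_true(all(co$survival$event))
  carrier <- co$truth$carrier[match(co$survival$sample_id, co$truth$sample_id)]
  # hazard ratio e: carrier mean survival should be clearly shorter
  expect_lt(mean(co$survival$duration[carrier]),
            0.6 * mean(co$survival$duration[!carrier]))

  bad <- cohort_spec(
    groups = spec$groups,
    survival = list(baseline_hazard = 1 / 1000,
                    coefficients = c("+9q" = 1))
  )
  expect_error(simulate_cohort(g, bad), "unknown event label")
})

test_that("cohort specs round-trip through YAML", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "purity_range: [0.6, 0.9]",
    "noise_sd: 0.2",
    "survival:",
    "  baseline_hazard: 0.001",
    "  censor_rate: 0.2",
    "  coefficients:",
    "    \"+5q\": 0.5",
    "groups:",
    "  - label: G1",
    "    subtype: CC",
    "    stage: S1a",
    "    n_samples: 4",
    "    events:",
    "      - {region: 3p, tumor_cn: 1, penetrance: 0.8}",
    "      - {region: 5q, tumor_cn: 3}"
  ), path)
  spec <- read_cohort_spec_yaml(path)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$noise_sd, 0.2)
  expect_equal(spec$purity_range, c(0.6, 0.9))
  expect_equal(spec$groups[[1]]$n, 4L)
  expect_equal(spec$groups[[1]]$events[[2]]$label, "+5q")
  expect_equal(spec$survival$coefficients, c("+5q" = 0.5))
  g <- tiny_genome()
  co <- simulate_cohort_seeded(g, spec, seed = 2)
  expect_length(co$profiles, 4L)
  expect_equal(nrow(co$survival), 4L)
})

test_that("packaged templates respect their declared structure", {
  tpl <- stage_template_spec(n_per_group = 3L)
  expect_equal(vapply(tpl$groups, `[[`, "", "label"), c("S1a", "S3b4"))
  s1a_labels <- vapply(tpl$groups[[1]]$events, `[[`, "", "label")
  expect_setequal(s1a_labels, c("-3p", "+5q", "+7", "-14"))
  s3b4_labels <- vapply(tpl$groups[[2]]$events, `[[`, "", "label")
  expect_true(all(s1a_labels %in% s3b4_labels))
  expect_length(s3b4_labels, 15L)

  sub <- subtype_template_spec(n_per_group = 2L)
  expect_setequal(vapply(sub$groups, `[[`, "", "subtype"),
                  c("CC", "PA", "CH", "ON"))
  expect_length(sub$groups[[4]]$events, 0L)
})
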