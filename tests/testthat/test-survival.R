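test_that("disease-specific survival handles death cause and censoring", {
  # disease death across a leap year: 366 days, event
  r1 <- build_dss("2000-01-01", "2001-01-01", "2001-01-01", TRUE)
  expect_equal(r1$duration, 366)
  expect_true(r1$event)

  # alive at last follow-up: censored
  r2 <- build_dss("2000-01-01", NA, "2003-01-01", FALSE)
  expect_equal(r2$duration, 1096)
  expect_false(r2$event)

  # death from another cause: censored at the death date
  r3 <- build_dss("2000-01-01", "2000-07-01", "2001-01-01", FALSE)
  expect_equal(r3$duration, 182)
  expect_false(r3$event)

  expect_error(build_dss("2000-01-01", "1999-01-01", "2000-06-01", TRUE),
               "precedes")
})

test_that("score and information match brute-force risk-set enumeration", {
  # 6-sample hand dataset
  x <- c(0.5, -1.2, 2.0, 0.3, -0.7, 1.1)
  time <- c(5, 8, 3, 12, 9, 6)
  event <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)
  want <- oracle_cox_UI(x, time, event)
  got <- cox_score_test(x, time, event)
  expect_equal(got$statistic, want$U^2 / want$I, tolerance = 1e-12)
  expect_equal(got$p_value, pchisq(want$U^2 / want$I, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_false(got$degenerate)

  # randomized instances, cross-checked against survival::coxph's score test
  skip_if_not_installed("survival")
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(8:20, 1)
    xs <- rnorm(n)
    ts <- rexp(n, 0.1)
    ev <- runif(n) < 0.7
    if (sum(ev) < 2) next
    w <- oracle_cox_UI(xs, ts, ev)
    fit <- cox_score_test(xs, ts, ev)
    expect_equal(fit$statistic, w$U^2 / w$I, tolerance = 1e-10)
    cp <- survival::coxph(survival::Surv(ts, ev) ~ xs, ties = "breslow")
    expect_equal(fit$statistic, unname(summary(cp)$sctest["test"]),
                 tolerance = 1e-6)
    # compare fitted coefficients only where the likelihood is well peaked
    # (near-monotone likelihoods have no stable finite maximum)
    if (abs(unname(coef(cp))) < 5) {
      expect_equal(fit$coefficient, unname(coef(cp)), tolerance = 1e-4)
    }
  }
})

test_that("degenerate covariates and empty event sets follow the contract", {
  expect_error(cox_score_test(c(1, 2, 3), c(1, 2, 3), c(FALSE, FALSE, FALSE)),
               "no events")
  d <- cox_score_test(c(1, 1, 1, 1), c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE))
  expect_true(d$degenerate)
  expect_equal(c(d$statistic, d$p_value, d$coefficient), c(0, 1, 0))
})

test_that("binary-covariate score test equals the logrank chi-square", {
  set.seed(32)
  for (rep in 1:50) {
    n <- sample(10:24, 1)
    grp <- rbinom(n, 1, 0.5)
    if (length(unique(grp)) < 2) grp[1:2] <- c(0, 1)
    ts <- rexp(n, 0.05)   # continuous: no ties
    ev <- runif(n) < 0.75
    if (sum(ev) < 3) ev[sample(n, 3)] <- TRUE
    fit <- cox_score_test(grp, ts, ev)
    expect_equal(fit$statistic, oracle_logrank(grp, ts, ev), tolerance = 1e-10)
  }
})

test_that("the resampled scan filters by IQR and averages over models", {
  set.seed(33)
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  wide <- rnorm(n, sd = 6)    # IQR well above 2.5
  narrow <- rnorm(n, sd = 0.5) # IQR well below 2.5
  sc <- score_matrix(cbind(b_wide = wide, b_narrow = narrow) |>
                       `rownames<-`(ids))
  rec <- data.frame(sample_id = ids, duration = rexp(n, 0.01),
                    event = runif(n) < 0.7)
  scan <- resampled_scan(sc, rec, n_models = 20L, seed = 5)
  expect_equal(scan$included, c(TRUE, FALSE))
  expect_true(is.na(scan$mean_neglog10_p[2]))
  expect_gt(scan$n_models_used[1], 0)
  expect_gte(scan$mean_neglog10_p[1], 0)

  # all bands under the IQR floor: empty included set
  low <- score_matrix(matrix(rnorm(n * 2, sd = 0.3), ncol = 2,
                             dimnames = list(ids, c("a", "b"))))
  scan_low <- resampled_scan(low, rec, n_models = 5L, seed = 5)
  expect_false(any(scan_low$included))
})

test_that("the scan is invariant to sample order and band order", {
  set.seed(34)
  n <- 50
  ids <- sprintf("s%02d", 1:n)
  sc <- score_matrix(matrix(rnorm(n * 3, sd = 6), ncol = 3,
                            dimnames = list(ids, c("1p1", "2q1", "3p1"))))
  rec <- data.frame(sample_id = ids, duration = rexp(n, 0.01),
                    event = runif(n) < 0.8)
  base <- resampled_scan(sc, rec, n_models = 10L, seed = 9)

  perm_s <- sample(n)
  sc2 <- score_matrix(unclass(sc)[perm_s, c(3, 1, 2)])
  rec2 <- rec[sample(n), ]
  shuf <- resampled_scan(sc2, rec2, n_models = 10L, seed = 9)
  reord <- shuf[match(base$band, shuf$band), ]
  expect_equal(base$mean_neglog10_p, reord$mean_neglog10_p)
  expect_equal(base$mean_coefficient, reord$mean_coefficient)
})

test_that("scan configuration is validated up front", {
  ids <- c("a", "b", "c", "d")
  sc <- score_matrix(matrix(rnorm(8, sd = 6), ncol = 2,
                            dimnames = list(ids, c("x", "y"))))
  rec <- data.frame(sample_id = ids, duration = 1:4,
                    event = c(TRUE, TRUE, TRUE, TRUE))
  expect_error(resampled_scan(sc, rec, subset_fraction = 0.5, seed = 1),
               "too small")
  rec2 <- rec; rec2$event <- c(TRUE, FALSE, FALSE, FALSE)
  expect_error(resampled_scan(sc, rec2, subset_fraction = 1, seed = 1),
               "fewer than 2 events")
  expect_error(resampled_scan(sc, rec[1:3, ], seed = 1), "no survival record")
})
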