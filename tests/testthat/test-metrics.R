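test_that("Brier score matches closed forms", {
  expect_equal(brier_score(c(0, 1, 1), c(0, 1, 1)), 0)
  y <- c(0, 1, 1, 0, 1)
  expect_equal(brier_score(rep(0.5, 5), y), 0.25)
  expect_equal(brier_score(c(0.2, 0.8), c(0, 1)), 0.04)
  expect_error(brier_score(numeric(0), numeric(0)), class = "oxrecal_metric_error")
})

test_that("AUC equals Mann-Whitney concordance with ties counted one half", {
  expect_equal(auc(c(0.1, 0.2, 0.3, 0.4), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.3, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_equal(auc(c(0.2, 0.4, 0.4, 0.8), c(0, 1, 0, 1)), 0.875)
  expect_error(auc(c(0.1, 0.2), c(1, 1)), class = "oxrecal_metric_error")
})

test_that("rank AUC equals brute-force pairs and trapezoidal area on random tied data", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(10:200, 1)
      # coarse grid scores force ties
      s <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
      y <- rbinom(n, 1, 0.3)
      if (sum(y) == 0 || sum(y) == n) next
      a <- auc(s, y)
      expect_equal(a, auc_pairs_oracle(s, y), tolerance = 1e-12)
      expect_equal(a, auc_trapezoid_oracle(s, y), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with pROC on a moderately sized cohort", {
  skip_if_not_installed("pROC")
  sim <- calibrated_cohort(500, seed = 31)
  r <- score_cohort(sim$cohort, sweden_coefs())$risk
  y <- sim$cohort$outcome
  expect_equal(auc(r, y),
               as.numeric(pROC::auc(pROC::roc(y, r, quiet = TRUE))),
               tolerance = 1e-12)
  ci <- auc_ci(r, y)
  pci <- as.numeric(pROC::ci.auc(pROC::roc(y, r, quiet = TRUE), method = "delong"))
  expect_equal(unname(ci), pci[c(2, 1, 3)], tolerance = 1e-10)
})

test_that("DeLong interval contains the point estimate and degenerates under separation", {
  s <- c(rep(0.1, 50), rep(0.9, 50))
  y <- rep(c(0, 1), each = 50)
  ci <- auc_ci(s, y)
  expect_equal(ci[["auc"]], 1)
  expect_equal(ci[["lower"]], 1)  # zero DeLong variance
  expect_equal(ci[["upper"]], 1)

  sim <- calibrated_cohort(300, seed = 17)
  r <- score_cohort(sim$cohort, sweden_coefs())$risk
  ci2 <- auc_ci(r, sim$cohort$outcome)
  expect_lte(ci2[["lower"]], ci2[["auc"]])
  expect_gte(ci2[["upper"]], ci2[["auc"]])
  expect_true(ci2[["lower"]] >= 0 && ci2[["upper"]] <= 1)
})

test_that("DeLong interval agrees with a seeded bootstrap on overlapping score distributions", {
  withr::with_seed(77, {
    s <- c(rnorm(500, 0, 1), rnorm(500, 0.6, 1))
    y <- rep(c(0, 1), each = 500)
  })
  dl <- auc_ci(s, y, method = "delong")
  bs <- auc_ci(s, y, method = "bootstrap", n_boot = 2000, seed = 99)
  expect_equal(dl[["lower"]], bs[["lower"]], tolerance = 0.02)
  expect_equal(dl[["upper"]], bs[["upper"]], tolerance = 0.02)
})

test_that("calibration intercept matches its constant-risk closed form and null simulation", {
  # constant risk equal to prevalence -> 0
  y <- rep(c(1, 0), c(30, 70))
  expect_equal(calibration_intercept(rep(0.3, 100), y), 0, tolerance = 1e-8)
  # constant risk 0.1, prevalence 0.5 -> logit(0.5) - logit(0.1)
  y2 <- rep(c(1, 0), 50)
  expect_equal(calibration_intercept(rep(0.1, 100), y2),
               qlogis(0.5) - qlogis(0.1), tolerance = 1e-8)
  # outcomes drawn from the risks themselves: CITL near 0
  sim <- calibrated_cohort(50000, seed = 41)
  r <- score_cohort(sim$cohort, sweden_coefs())$risk
  expect_lt(abs(calibration_intercept(r, sim$cohort$outcome)), 0.05)
})

test_that("calibration slope recovers 1 under the null and a compressed truth", {
  sim <- calibrated_cohort(50000, seed = 43)
  r <- score_cohort(sim$cohort, sweden_coefs())$risk
  y <- sim$cohort$outcome
  expect_equal(calibration_slope(r, y), 1, tolerance = 0.05)

  # logit-scale compression by 0.8: outcomes from squeezed risks
  lg <- qlogis(r)
  squeezed <- plogis(mean(lg) + 0.8 * (lg - mean(lg)))
  y2 <- withr::with_seed(44, rbinom(length(squeezed), 1, squeezed))
  slope <- calibration_slope(r, y2)
  expect_equal(slope, 0.8, tolerance = 0.05)
  # label swap flips the sign
  expect_lt(calibration_slope(r, 1 - y2), 0)
  expect_error(calibration_slope(rep(0.2, 50), rbinom(50, 1, 0.2)),
               class = "oxrecal_fit_error")
})

test_that("E:O ratio is the expected over observed event count", {
  expect_equal(eo_ratio(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(eo_ratio(c(0.5, 0.5), c(1, 0)), 1)
  expect_equal(eo_ratio(rep(0.1, 10), rep(c(1, 0), c(2, 8))), 0.5)
  expect_error(eo_ratio(rep(0.1, 5), rep(0, 5)), class = "oxrecal_metric_error")
})

test_that("quantile calibration bins partition the cohort and sit on the diagonal when calibrated", {
  sim <- calibrated_cohort(20000, seed = 47)
  r <- score_cohort(sim$cohort, sweden_coefs())$risk
  bins <- calibration_bins(r, sim$cohort$outcome)
  expect_equal(sum(bins$n), 20000)
  expect_true(all(bins$observed >= 0 & bins$observed <= 1))
  expect_true(!is.unsorted(bins$mean_predicted))
  # each bin observed within 4 binomial SDs of its mean predicted risk
  sd4 <- 4 * sqrt(bins$mean_predicted * (1 - bins$mean_predicted) / bins$n)
  expect_true(all(abs(bins$observed - bins$mean_predicted) < sd4))

  # all risks equal: every bin mean equals the common risk
  eq <- calibration_bins(rep(0.2, 40), rep(c(0, 1), 20))
  expect_true(all(eq$mean_predicted == 0.2))
  # n = n_bins: one member each
  one <- calibration_bins(seq(0.1, 0.9, length.out = 10), rep(c(0, 1), 5))
  expect_true(all(one$n == 1))
  expect_error(calibration_bins(runif(10), rbinom(10, 1, 0.5), n_bins = 1),
               class = "oxrecal_metric_error")
})

test_that("threshold metrics tabulate the 2x2 table with Wilson intervals", {
  tm <- threshold_metrics(c(0.9, 0.9, 0.1, 0.1), c(1, 0, 1, 0), 0.5)
  expect_equal(tm[, c("tp", "fp", "tn", "fn")],
               data.frame(tp = 1L, fp = 1L, tn = 1L, fn = 1L),
               ignore_attr = TRUE)
  expect_equal(unlist(tm[, c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 0.5, specificity = 0.5, ppv = 0.5, npv = 0.5))

  # treat-all limit: epsilon threshold
  r <- c(0.2, 0.6, 0.4, 0.8); y <- c(0, 1, 1, 0)
  all_pos <- threshold_metrics(r, y, 1e-9)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  expect_equal(all_pos$ppv, mean(y))

  # complement symmetry: flipping outcomes and the classifier swaps the pairs
  a <- threshold_metrics(r, y, 0.5)
  b <- threshold_metrics(1 - r, 1 - y, 0.5 + 1e-12)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$ppv, b$npv)

  # no predicted positives -> NA PPV, not an error
  none <- threshold_metrics(c(0.1, 0.2, 0.3, 0.2), c(0, 1, 0, 1), 0.9)
  expect_true(is.na(none$ppv))
  expect_equal(none$sensitivity, 0)
  expect_error(threshold_metrics(r, y, 1.5), class = "oxrecal_metric_error")
})

test_that("Wilson intervals stay in [0,1] and contain the point estimate", {
  withr::with_seed(7, {
    for (i in 1:50) {
      n <- sample(1:40, 1)
      x <- sample(0:n, 1)
      w <- wilson_interval(x, n)
      expect_gte(w[["estimate"]], w[["lower"]])
      expect_lte(w[["estimate"]], w[["upper"]])
      expect_gte(w[["lower"]], 0)
      expect_lte(w[["upper"]], 1)
    }
  })
})

test_that("a report composes its component metrics exactly", {
  sim <- calibrated_cohort(2000, seed = 53)
  r <- score_cohort(sim$cohort, sweden_coefs())$risk
  y <- sim$cohort$outcome
  rep <- build_report(r, y, label = "composition")
  expect_equal(rep$brier, brier_score(r, y))
  expect_equal(rep$auc, auc(r, y))
  expect_equal(rep$citl, calibration_intercept(r, y))
  expect_equal(rep$slope, calibration_slope(r, y))
  expect_equal(rep$eo_ratio, eo_ratio(r, y))
  expect_equal(rep$incidence, mean(y))
  expect_identical(rep$thresholds$threshold, c(0.05, 0.10, 0.15, 0.20))
  expect_error(build_report(r, y, thresholds = c(0.2, 0.1)),
               class = "oxrecal_metric_error")
})

test_that("calibrated informative predictors beat the prevalence predictor on Brier", {
  sim <- calibrated_cohort(50000, seed = 59)
  r <- score_cohort(sim$cohort, sweden_coefs())$risk
  y <- sim$cohort$outcome
  prev <- mean(y)
  # analytic decomposition under calibration: Brier ~ mean(r(1-r))
  expect_equal(brier_score(r, y), mean(r * (1 - r)), tolerance = 0.01)
  expect_lte(brier_score(r, y), brier_score(rep(prev, length(y)), y))
})
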