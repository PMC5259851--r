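test_that("per-interval exposure time follows the three-case definition", {
  cp <- c(5, 10, 15, 20)
  expect_equal(exposure_time(7, cp), c(5, 2, 0, 0))
  expect_equal(exposure_time(0, cp), c(0, 0, 0, 0))
  expect_equal(exposure_time(20, cp), c(5, 5, 5, 5))
  expect_equal(exposure_time(25, cp), c(5, 5, 5, 5))  # capped at a_J
  # components always sum to min(t, a_J)
  set.seed(1)
  tt <- runif(50, 0, 30)
  expect_equal(rowSums(exposure_time(tt, cp)), pmin(tt, 20))
  expect_error(exposure_time(-1, cp), "nonnegative")
  expect_error(exposure_time(1, c(5, 5)), "strictly increasing")
})

test_that("single-interval fits reduce to closed-form exponential MLEs", {
  s <- ph_sample(n = 400, seed = 10)
  # beta forced to zero: pooled rate = events / person-time
  f0 <- fit_pch(s, cutpoints = 20, with_exposure = FALSE)
  expect_equal(exp(f0$alpha), sum(s$event) / sum(s$time))
  # with exposure: group-specific rates
  f1 <- fit_pch(s, cutpoints = 20)
  for (g in 0:1) {
    rate <- sum(s$event[s$exposure == g]) / sum(s$time[s$exposure == g])
    expect_equal(exp(f1$alpha + g * f1$beta), rate, tolerance = 1e-8)
  }
})

test_that("constant-hazard data recover beta and the calibrated hazard", {
  s <- ph_sample(n = 10000, seed = 12)
  fit <- fit_pch(s)
  se_beta <- sqrt(fit$vcov[5, 5])
  expect_lt(abs(fit$beta - log(2)), 3 * se_beta)
  # true baseline hazard is ln(2)/15 in every interval
  for (j in 1:4) {
    expect_lt(abs(fit$alpha[j] - log(log(2) / 15)),
              3 * sqrt(fit$vcov[j, j]))
  }
})

test_that("empty intervals and out-of-range requests are explicit errors", {
  # no events beyond t = 6, but person-time in later intervals
  s <- cohort_sample(c(1, 2, 3, 18, 19, 20), c(1, 1, 1, 0, 0, 0),
                     c(0, 1, 0, 1, 0, 1))
  expect_error(fit_pch(s), class = "paftime_empty_interval")
  s2 <- ph_sample(n = 300, seed = 3)
  expect_error(ar_pch(s2, times = 25), "extrapolation")
  expect_error(fit_pch(cohort_sample(25, 1, 0), cutpoints = c(5, 10)),
               "exceed")
})

test_that("parametric A(t) is consistent and zero under a null fit", {
  s <- null_effect_sample()
  curve <- ar_pch(s, c(2, 5), cutpoints = 8, variance = "none")
  expect_equal(curve$estimate, c(0, 0), tolerance = 1e-8)

  cfg <- scenario_config(model = "ph", gamma = 1, n = 20000, seed = 55)
  big <- simulate_cohort(cfg)
  truth <- theoretical_ar(cfg, c(5, 20))
  est <- ar_pch(big, c(5, 20))
  expect_true(all(abs(est$estimate - truth) < 3 * est$se))
})

test_that("refining cutpoints reduces misspecification bias", {
  cfg <- scenario_config(model = "ph", gamma = 4/3, n = 30000, seed = 9)
  s <- simulate_cohort(cfg)
  truth <- theoretical_ar(cfg, 5)
  coarse <- ar_pch(s, 5, cutpoints = 20, variance = "none")$estimate
  fine <- ar_pch(s, 5, cutpoints = seq(2.5, 20, 2.5),
                 variance = "none")$estimate
  expect_lt(abs(fine - truth), abs(coarse - truth))
})

test_that("delta-method SEs agree with the bootstrap within 15%", {
  s <- ph_sample(n = 1000, seed = 11)
  a <- ar_pch(s, c(5, 10, 15, 20), variance = "delta")
  b <- ar_pch(s, c(5, 10, 15, 20), variance = "bootstrap",
              boot_reps = 300, seed = 3)
  expect_true(all(abs(a$se / b$se - 1) < 0.15))
})
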