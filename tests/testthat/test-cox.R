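test_that("partial likelihood fit matches a brute-force grid search", {
  # four subjects, all events, alternating exposure: bounded maximum
  s <- cohort_sample(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
  # textbook Breslow partial likelihood, written out risk set by risk set
  pl <- function(b) {
    eb <- exp(b)
    log(eb / (2 * eb + 2)) + log(1 / (eb + 2)) + log(eb / (eb + 1)) + 0
  }
  grid <- seq(-4, 4, by = 1e-4)
  bhat_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  fit <- fit_cox(s)
  expect_equal(fit$beta, bhat_grid, tolerance = 1e-3)
  # Breslow baseline increments at the event times
  eb <- exp(fit$beta)
  expect_equal(fit$baseline$dhaz,
               c(1 / (2 * eb + 2), 1 / (eb + 2), 1 / (eb + 1), 1))
})

test_that("degenerate fits error as specified", {
  no_events <- cohort_sample(c(1, 2), c(0, 0), c(0, 1))
  expect_error(fit_cox(no_events), "no events")
  one_level <- cohort_sample(c(1, 2), c(1, 1), c(0, 0))
  expect_error(fit_cox(one_level), "single level")
  monotone <- cohort_sample(c(1, 2, 3, 4), c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_error(fit_cox(monotone), "monotone")
})

test_that("null and ln(2) effects are recovered", {
  s0 <- ph_sample(n = 5000, seed = 21, beta = 0)
  f0 <- fit_cox(s0)
  expect_lt(abs(f0$beta), 3 * f0$se_beta)

  s1 <- ph_sample(n = 10000, seed = 22)
  f1 <- fit_cox(s1)
  expect_lt(abs(f1$beta - log(2)), 3 * f1$se_beta)
})

test_that("semiparametric A(t) matches a hand-computed toy example", {
  s <- cohort_sample(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 0, 1, 0))
  fit <- fit_cox(s)
  eb <- exp(fit$beta)
  t0 <- 2.5
  L0 <- 1 / (2 * eb + 2) + 1 / (eb + 2)  # Breslow cum. hazard at t = 2.5
  S0 <- exp(-L0)
  S <- mean(exp(-exp(fit$beta * s$exposure) * L0))
  expect_equal(ar_cox(s, t0, variance = "none")$estimate,
               1 - (1 - S0) / (1 - S))
})

test_that("exact null fit gives A(t) identically zero", {
  s <- null_effect_sample()
  fit <- fit_cox(s)
  expect_equal(fit$beta, 0, tolerance = 1e-8)
  curve <- ar_cox(s, c(2, 5, 7), variance = "none", fit = fit)
  expect_equal(curve$estimate, c(0, 0, 0), tolerance = 1e-8)
})

test_that("all-unexposed samples yield a zero AR curve wherever defined", {
  s <- cohort_sample(c(1, 2, 3, 4), c(0, 1, 1, 0), rep(0L, 4))
  curve <- suppressWarnings(ar_cox(s, c(0.5, 3)))
  expect_true(is.na(curve$estimate[1]))
  expect_equal(curve$estimate[2], 0)
})

test_that("semiparametric A(t) is consistent under proportional hazards", {
  cfg <- scenario_config(model = "ph", gamma = 1, n = 20000, seed = 44)
  s <- simulate_cohort(cfg)
  truth <- theoretical_ar(cfg, c(5, 20))
  curve <- ar_cox(s, c(5, 20))
  expect_true(all(abs(curve$estimate - truth) < 3 * curve$se))
})

test_that("NPH data bias the Cox AR upward at the end of follow-up", {
  cfg <- scenario_config(model = "nph", n = 20000, seed = 45)
  s <- simulate_cohort(cfg)
  truth <- theoretical_ar(cfg, 20)
  curve <- ar_cox(s, 20)
  # systematic misspecification bias (~ +0.03) far exceeds sampling noise
  expect_gt(curve$estimate - truth, 0.015)
})

test_that("influence-function SEs agree with the bootstrap", {
  s <- ph_sample(n = 600, seed = 18)
  a <- ar_cox(s, c(5, 10, 15, 20), variance = "if")
  b <- ar_cox(s, c(5, 10, 15, 20), variance = "bootstrap",
              boot_reps = 200, seed = 2)
  expect_true(all(abs(a$se / b$se - 1) < 0.15))
})

test_that("administrative truncation restricts the data used", {
  s <- ph_sample(n = 2000, seed = 19)
  full <- fit_cox(s)
  half <- fit_cox(s, max_time = 10)
  expect_lt(max(half$baseline$time), 10 + 1e-12)
  expect_gt(half$se_beta, full$se_beta)  # fewer events, less information
})
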