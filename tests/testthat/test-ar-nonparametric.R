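test_that("identical survival in both arms gives A(t) = 0 exactly", {
  s <- null_effect_sample()
  for (w in c("km", "wkm")) {
    curve <- ar_nonparametric(s, times = c(2, 5, 7), weighting = w,
                              variance = "none")
    expect_equal(curve$estimate, c(0, 0, 0))
  }
})

test_that("nonparametric A(t) converges to the closed-form truth", {
  cfg <- scenario_config(model = "ph", gamma = 1, n = 20000, seed = 33)
  s <- simulate_cohort(cfg)
  truth <- theoretical_ar(cfg, c(5, 10, 15, 20))
  for (w in c("km", "wkm")) {
    curve <- ar_nonparametric(s, c(5, 10, 15, 20), weighting = w)
    # within 3 estimated SEs of the truth at every time
    expect_true(all(abs(curve$estimate - truth) < 3 * curve$se))
    expect_true(all(curve$estimate <= 1))
  }
})

test_that("A(t) is undefined before the first event and reported missing", {
  s <- cohort_sample(c(2, 3, 4, 5), c(0, 1, 1, 1), c(0, 1, 0, 1))
  expect_warning(curve <- ar_nonparametric(s, times = c(1, 4),
                                           variance = "none"),
                 "undefined")
  expect_true(is.na(curve$estimate[1]))
  expect_false(is.na(curve$estimate[2]))
})

test_that("a sample without baseline subjects is rejected", {
  # the container's contiguity invariant already forbids a cohort whose
  # strata do not start at the baseline label 0
  expect_error(cohort_sample(c(1, 2), c(1, 1), c(1, 1)), "contiguous")
})

test_that("negative early estimates are returned as-is", {
  # exposed arm has later events than unexposed: S0 < S early on
  s <- cohort_sample(c(1, 1.5, 2, 8, 9, 10), c(1, 1, 1, 1, 1, 1),
                     c(0, 0, 0, 1, 1, 1))
  curve <- ar_nonparametric(s, times = 3, variance = "none")
  expect_lt(curve$estimate, 0)
})

test_that("swapping exposure labels leaves the pooled KM unchanged", {
  s <- ph_sample(n = 300, seed = 5)
  flipped <- cohort_sample(s$time, s$event, 1L - s$exposure)
  grid <- seq(0.5, 20, by = 0.5)
  expect_equal(eval_surv(km_survival(s), grid),
               eval_surv(km_survival(flipped), grid))
})

test_that("influence-function SEs agree with the bootstrap", {
  s <- ph_sample(n = 600, seed = 17)
  for (w in c("km", "wkm")) {
    a <- ar_nonparametric(s, c(5, 10, 15), weighting = w, variance = "if")
    b <- ar_nonparametric(s, c(5, 10, 15), weighting = w,
                          variance = "bootstrap", boot_reps = 200, seed = 1)
    expect_true(all(abs(a$se / b$se - 1) < 0.15))
  }
})

test_that("AR curve CSV round trip preserves values", {
  s <- ph_sample(n = 200, seed = 2)
  curve <- ar_nonparametric(s, c(5, 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ar_curve(curve, path)
  back <- read_ar_curve(path)
  expect_equal(back$estimate, curve$estimate, tolerance = 1e-12)
  expect_equal(back$se, curve$se, tolerance = 1e-12)
  expect_equal(back$ci_low, curve$ci_low, tolerance = 1e-12)
})
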