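test_that("Weibull scale calibration puts the unexposed median at 15 years", {
  for (g in c(3/4, 1, 4/3)) {
    cfg <- scenario_config(model = "ph", gamma = g)
    expect_equal(theoretical_survival(cfg, 15, "unexposed"), 0.5)
  }
  expect_equal(calibrate_theta(1), 15 / log(2))
  # NPH model: (1 + 2 * 0.1 * 15)^(-1/2) = 0.5
  expect_equal(theoretical_survival(scenario_config(model = "nph"), 15,
                                    "unexposed"), 0.5)
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- scenario_config(model = "ph", n = 500, seed = 123)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  cfg2 <- scenario_config(model = "nph", n = 500, seed = 123)
  expect_identical(simulate_cohort(cfg2), simulate_cohort(cfg2))
})

test_that("generated event times follow the closed-form distributions", {
  # near-infinite censoring horizon isolates the latent event times
  for (model in c("ph", "nph")) {
    cfg <- scenario_config(model = model, gamma = 4/3, n = 100000,
                           seed = 77, tau = 1e9)
    s <- simulate_cohort(cfg)
    expect_gt(mean(s$event), 0.999)
    for (arm in 0:1) {
      tt <- s$time[s$exposure == arm]
      cdf <- function(x) 1 - theoretical_survival(
        cfg, x, if (arm == 0) "unexposed" else "exposed")
      ks <- suppressWarnings(stats::ks.test(tt, cdf))
      expect_gt(ks$p.value, 0.001)
    }
  }
})

test_that("unexposed empirical medians sit at 15 years in both models", {
  for (model in c("ph", "nph")) {
    cfg <- scenario_config(model = model, n = 100000, seed = 78, tau = 1e9)
    s <- simulate_cohort(cfg)
    med <- median(s$time[s$exposure == 0])
    expect_lt(abs(med - 15), 0.5)
  }
})

test_that("censoring fractions fall in the study's reported range", {
  cfg <- scenario_config(model = "ph", gamma = 1, n = 1000, seed = 79)
  frac <- vapply(1:100, function(r)
    1 - mean(simulate_cohort(cfg, seed = r)$event), numeric(1))
  expect_true(all(frac > 0.42 & frac < 0.73))
})

test_that("the NPH hazard ratio decays from 2 toward 1 over follow-up", {
  cfg <- scenario_config(model = "nph", n = 50000, seed = 80)
  s <- simulate_cohort(cfg)
  window_hr <- function(lo, hi) {
    rate <- function(z) {
      pt <- sum(pmax(0, pmin(s$time[s$exposure == z], hi) - lo))
      ev <- sum(s$event == 1 & s$exposure == z & s$time > lo & s$time <= hi)
      ev / pt
    }
    rate(1) / rate(0)
  }
  early <- window_hr(0, 5)
  late <- window_hr(15, 20)
  expect_gt(early, late + 0.3)
  expect_lt(late, 1.3)
})

test_that("theoretical AR has the documented shape and edge behaviour", {
  cfg <- scenario_config(model = "ph", gamma = 1)
  expect_error(theoretical_ar(cfg, 0), "undefined")
  null <- scenario_config(model = "ph", beta = 0)
  expect_equal(theoretical_ar(null, c(1, 5, 20)), c(0, 0, 0))
  # time-dependent truth never exceeds the global truth under PH, beta > 0
  tt <- seq(0.5, 20, by = 0.5)
  expect_true(all(theoretical_ar(cfg, tt) <= theoretical_global_ar(cfg)))
})

test_that("scenario configuration files round-trip through YAML and JSON", {
  cfg <- list(model = "nph", beta = 0.5, q = 0.25, n = 250, reps = 3,
              seed = 9, tau = 20, lambda0 = 0.1)
  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, fy)
  cy <- read_scenario_config(fy)
  expect_equal(cy$q, 0.25)
  expect_equal(cy$model, "nph")
  fj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, fj, auto_unbox = TRUE)
  cj <- read_scenario_config(fj)
  expect_equal(unclass(cj), unclass(cy))
  # unknown keys are rejected
  cfg$typo <- 1
  yaml::write_yaml(cfg, fy)
  expect_error(read_scenario_config(fy), "typo")
})
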