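#' Scenario configuration for cohort simulation
#'
#' Bundles the generator parameters of the simulation study.  Under
#' proportional hazards (`model = "ph"`) event times follow a Weibull
#' proportional hazards model with baseline hazard
#' \eqn{\lambda_0(t) = \gamma \theta^{-\gamma} t^{\gamma - 1}} and hazard
#' ratio \eqn{e^\beta} for the exposed; the scale \eqn{\theta} is
#' calibrated so the unexposed median survival equals `median_surv` years
#' (15 by default).  Under nonproportional hazards (`model = "nph"`) the
#' cumulative hazard is \eqn{\Lambda(t \mid Z) = G(\lambda_0 t e^{\beta Z})}
#' with the logarithmic transformation \eqn{G(t) = \ln(1 + 2t)/2}, under
#' which the hazard ratio of exposed to unexposed decreases from
#' \eqn{e^\beta} toward 1 over time.  Censoring times are uniform on
#' \eqn{[0, \tau]}, independent of exposure and event times.
#'
#' @param model `"ph"` or `"nph"`.
#' @param gamma Weibull shape (PH only); 1 gives a constant baseline
#'   hazard, 4/3 increasing, 3/4 decreasing.
#' @param beta log hazard ratio (ln 2 by default).
#' @param q exposure probability (Bernoulli draw per subject).
#' @param n sample size per replicate.
#' @param reps number of Monte Carlo replicates.
#' @param seed master RNG seed.
#' @param tau maximal follow-up (years); censoring is uniform on
#'   \eqn{[0, \tau]}.
#' @param lambda0 rate parameter of the NPH model (per year).
#' @param admin_censor_time optional additional administrative censoring
#'   time (e.g. \eqn{\tau/4} or \eqn{\tau/2}).
#' @param median_surv target unexposed median survival used to calibrate
#'   \eqn{\theta} (PH).
#' @return A list of class `"scenario_config"`; for PH models the derived
#'   Weibull scale is stored as `theta`.
#' @examples
#' scenario_config(model = "ph", gamma = 1, n = 1000, seed = 1)
#' @export
scenario_config <- function(model = c("ph", "nph"), gamma = 1,
                            beta = log(2), q = 0.5, n = 1000, reps = 1000,
                            seed = 1, tau = 20, lambda0 = 0.1,
                            admin_censor_time = NULL, median_surv = 15) {
  model <- match.arg(tolower(model), c("ph", "nph"))
  stopifnot(gamma > 0, q > 0, q < 1, n >= 1, reps >= 1, tau > 0,
            lambda0 > 0, median_surv > 0)
  if (!is.null(admin_censor_time))
    stopifnot(admin_censor_time > 0, admin_censor_time <= tau)
  cfg <- list(model = model, gamma = gamma, beta = beta, q = q,
              n = as.integer(n), reps = as.integer(reps),
              seed = as.integer(seed), tau = tau, lambda0 = lambda0,
              admin_censor_time = admin_censor_time,
              median_surv = median_surv,
              theta = if (model == "ph") calibrate_theta(gamma, median_surv)
                      else NA_real_)
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario [%s]: beta = %.4f, q = %.2f, n = %d, reps = %d, tau = %g, seed = %d\n",
              toupper(x$model), x$beta, x$q, x$n, x$reps, x$tau, x$seed))
  if (x$model == "ph")
    cat(sprintf("Weibull baseline: gamma = %.4g, theta = %.4f (median %g y)\n",
                x$gamma, x$theta, x$median_surv))
  else
    cat(sprintf("NPH transformation G(t) = ln(1+2t)/2, lambda0 = %g\n",
                x$lambda0))
  if (!is.null(x$admin_censor_time))
    cat(sprintf("Administrative censoring at %g years\n", x$admin_censor_time))
  invisible(x)
}

#' Read a scenario configuration file (YAML or JSON)
#'
#' Recognized keys: `model`, `gamma`, `beta`, `q`, `n`, `reps`, `seed`,
#' `tau`, `lambda0`, `admin_censor_time`.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- c("model", "gamma", "beta", "q", "n", "reps", "seed", "tau",
             "lambda0", "admin_censor_time")
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  do.call(scenario_config, vals)
}

#' Calibrate the Weibull scale to a target median
#'
#' Returns \eqn{\theta} such that the unexposed Weibull survival
#' \eqn{S_0(t) = \exp\{-(t/\theta)^\gamma\}} equals 0.5 at the target
#' median: \eqn{\theta = \mathrm{median} / (\ln 2)^{1/\gamma}}.
#'
#' @param gamma Weibull shape, > 0.
#' @param median target median survival (years), 15 by default.
#' @return The scale parameter \eqn{\theta}.
#' @examples
#' calibrate_theta(1)  # 15 / ln 2
#' @export
calibrate_theta <- function(gamma, median = 15) {
  stopifnot(gamma > 0, median > 0)
  median / log(2)^(1 / gamma)
}

#' Simulate one cohort replicate
#'
#' Draws, in fixed order, the exposure indicators
#' (\eqn{Z \sim} Bernoulli(`q`)), the event times by inverse-CDF transform
#' of one uniform draw per subject, and the uniform censoring times on
#' \eqn{[0, \tau]}.  Under PH the event-time inverse is
#' \eqn{T = \theta\,[-\ln U / e^{\beta Z}]^{1/\gamma}}, which reproduces
#' \eqn{S(t \mid Z) = \exp\{-(t/\theta)^\gamma e^{\beta Z}\}}; under NPH it
#' is \eqn{T = G^{-1}(-\ln U) / (\lambda_0 e^{\beta Z})} with
#' \eqn{G^{-1}(y) = (e^{2y} - 1)/2}.  Ties between an event and a censoring
#' time (probability zero) count as events.
#'
#' @param config a [scenario_config()].
#' @param seed RNG seed for this replicate; defaults to `config$seed`.
#' @return A [cohort_sample()] of size `config$n`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  n <- config$n
  z <- rbinom(n, 1L, config$q)
  u <- runif(n)
  tev <- if (config$model == "ph") {
    config$theta * (-log(u) / exp(config$beta * z))^(1 / config$gamma)
  } else {
    (exp(-2 * log(u)) - 1) / (2 * config$lambda0 * exp(config$beta * z))
  }
  cens <- runif(n, 0, config$tau)
  if (!is.null(config$admin_censor_time))
    cens <- pmin(cens, config$admin_censor_time)
  time <- pmin(tev, cens)
  event <- as.integer(tev <= cens)
  cohort_sample(time, event, z)
}

#' Closed-form survival functions of the simulation models
#'
#' @param config a [scenario_config()].
#' @param t times, \eqn{\ge 0}.
#' @param arm `"unexposed"` (\eqn{S_0}), `"exposed"`, or `"population"`
#'   (the q-mixture \eqn{S = (1-q) S_0 + q S_1}).
#' @return Survival probabilities.
#' @export
theoretical_survival <- function(config, t,
                                 arm = c("unexposed", "exposed",
                                         "population")) {
  stopifnot(inherits(config, "scenario_config"))
  arm <- match.arg(arm)
  if (any(t < 0)) stop("t must be nonnegative")
  cum0 <- if (config$model == "ph") (t / config$theta)^config$gamma
          else log(1 + 2 * config$lambda0 * t) / 2
  cum1 <- if (config$model == "ph") cum0 * exp(config$beta)
          else log(1 + 2 * config$lambda0 * t * exp(config$beta)) / 2
  switch(arm,
         unexposed = exp(-cum0),
         exposed = exp(-cum1),
         population = (1 - config$q) * exp(-cum0) + config$q * exp(-cum1))
}

#' Closed-form theoretical attributable risk
#'
#' The true \eqn{A(t) = 1 - (1 - S_0(t)) / (1 - S(t))} of the configured
#' generating model, with \eqn{S_0} and \eqn{S} in closed form (Weibull for
#' PH, logarithmic transformation model for NPH).  Undefined at \eqn{t = 0}
#' (0/0).
#'
#' @param config a [scenario_config()].
#' @param t evaluation times, > 0 (vectorized).
#' @return The true attributable risk at each `t`.
#' @examples
#' cfg <- scenario_config(model = "ph", gamma = 1)
#' round(theoretical_ar(cfg, c(5, 10, 15, 20)), 3)  # 0.284 0.240 0.200 0.166
#' @export
theoretical_ar <- function(config, t) {
  stopifnot(inherits(config, "scenario_config"))
  if (any(t <= 0)) stop("A(t) is undefined at t = 0; use t > 0")
  S0 <- theoretical_survival(config, t, "unexposed")
  S <- theoretical_survival(config, t, "population")
  1 - (1 - S0) / (1 - S)
}

#' Theoretical global attributable risk
#'
#' The single-number truth \eqn{q(e^\beta - 1) / \{1 + q(e^\beta - 1)\}}
#' corresponding to the simpler prevalence-times-relative-risk estimator.
#'
#' @param config a [scenario_config()].
#' @return The global attributable risk.
#' @export
theoretical_global_ar <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  simpler_ar(config$q, exp(config$beta))
}
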