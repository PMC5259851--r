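#' Single-number attributable risk from prevalence and relative risk
#'
#' The classical epidemiological formula for a binary exposure,
#' \deqn{AR = \frac{q (RR - 1)}{1 + q (RR - 1)},}
#' with `q` the exposure prevalence and `RR` the relative risk (hazard
#' ratio under proportional hazards).
#'
#' @param q exposure prevalence in \[0, 1\].
#' @param rr relative risk, > 0.
#' @return The attributable risk (a number < 1).
#' @examples
#' simpler_ar(0.5, 2)  # 1/3
#' @export
simpler_ar <- function(q, rr) {
  if (any(q < 0 | q > 1)) stop("q must lie in [0, 1]")
  if (any(rr <= 0)) stop("rr must be positive")
  denom <- 1 + q * (rr - 1)
  if (any(denom <= 0))
    stop("1 + q(RR - 1) <= 0: attributable risk undefined")
  q * (rr - 1) / denom
}

#' Multi-category attributable risk (person-time formula)
#'
#' The general form
#' \deqn{AR = \frac{\sum_k q_k (RR_k - 1)}{1 + \sum_k q_k (RR_k - 1)}}
#' over \eqn{K + 1} exposure categories, as a pure function of the
#' category prevalences and relative risks (no cohort fitting).
#'
#' @param qk prevalences per category (nonnegative, summing to \eqn{\le 1};
#'   the baseline category may be included with \eqn{RR_0 = 1}).
#' @param rrk relative risks per category, > 0.
#' @return The attributable risk.
#' @export
spiegelman_ar <- function(qk, rrk) {
  if (length(qk) != length(rrk)) stop("qk and rrk must have equal length")
  if (any(qk < 0) || sum(qk) > 1 + 1e-9) stop("invalid prevalences qk")
  if (any(rrk <= 0)) stop("rrk must be positive")
  s <- sum(qk * (rrk - 1))
  if (1 + s <= 0) stop("1 + sum qk(RRk - 1) <= 0: attributable risk undefined")
  s / (1 + s)
}

#' Global attributable risk estimate from a cohort
#'
#' Fits a Cox model for the hazard ratio and plugs it, together with an
#' exposure-prevalence estimate, into [simpler_ar()].  The prevalence is
#' either the proportion of exposed subjects at baseline
#' (`prevalence = "baseline"`) or the exposed share of total person-years
#' (`prevalence = "person_years"`, the person-time variant).  The default
#' standard error is a delta-method combination of the prevalence variance
#' (binomial or person-time influence function) and the Cox variance of
#' \eqn{\hat\beta}, treating the two as asymptotically independent;
#' bootstrap is available as a cross-check.
#'
#' @param sample a [cohort_sample()].
#' @param prevalence `"baseline"` or `"person_years"`.
#' @param variance `"delta"` (default), `"bootstrap"` or `"none"`.
#' @param boot_reps,seed bootstrap controls.
#' @param conf_level nominal confidence level.
#' @return An object of class `"global_ar"` with fields `estimate`, `se`,
#'   `ci_low`, `ci_high`, `q`, `rr`, `prevalence`.
#' @export
global_ar_from_cohort <- function(sample,
                                  prevalence = c("baseline", "person_years"),
                                  variance = c("delta", "bootstrap", "none"),
                                  boot_reps = 200, seed = NULL,
                                  conf_level = 0.95) {
  stopifnot(inherits(sample, "cohort_sample"))
  prevalence <- match.arg(prevalence)
  variance <- match.arg(variance)
  n <- nrow(sample)

  if (all(sample$exposure == 0L)) {
    return(structure(list(estimate = 0, se = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, q = 0, rr = NA_real_,
                          prevalence = prevalence, conf_level = conf_level,
                          n = n),
                     class = "global_ar"))
  }

  fit <- fit_cox(sample)
  rr <- exp(fit$beta)
  if (prevalence == "baseline") {
    q <- mean(sample$exposure)
    var_q <- q * (1 - q) / n
  } else {
    q <- sum(sample$time * sample$exposure) / sum(sample$time)
    ifq <- (sample$exposure - q) * sample$time / mean(sample$time)
    var_q <- sum(ifq^2) / n^2
  }
  est <- simpler_ar(q, rr)

  se <- NA_real_
  if (variance == "delta") {
    denom <- 1 + q * (rr - 1)
    dq <- (rr - 1) / denom^2
    db <- q * rr / denom^2  # d/d beta, rr = e^beta
    se <- sqrt(dq^2 * var_q + db^2 * fit$var_beta)
  } else if (variance == "bootstrap") {
    if (!is.null(seed)) set.seed(seed)
    reps <- replicate(boot_reps, {
      idx <- sample.int(n, n, replace = TRUE)
      bs <- cohort_sample(sample$time[idx], sample$event[idx],
                          sample$exposure[idx], sample$stratum[idx])
      tryCatch(global_ar_from_cohort(bs, prevalence = prevalence,
                                     variance = "none")$estimate,
               error = function(e) NA_real_)
    })
    se <- sd(reps, na.rm = TRUE)
  }
  ci <- wald_ci(est, se, level = conf_level)
  structure(list(estimate = est, se = se, ci_low = ci$lower,
                 ci_high = ci$upper, q = q, rr = rr,
                 prevalence = prevalence, conf_level = conf_level, n = n),
            class = "global_ar")
}

#' @export
print.global_ar <- function(x, ...) {
  cat(sprintf(
    "Global attributable risk (%s prevalence): %.4f (SE %s)\n",
    x$prevalence, x$estimate,
    if (is.na(x$se)) "n/a" else sprintf("%.4f", x$se)))
  if (!is.na(x$ci_low))
    cat(sprintf("%d%% CI: %.4f to %.4f\n", round(100 * x$conf_level),
                x$ci_low, x$ci_high))
  cat(sprintf("q = %.4f, RR = %.4f, n = %d\n", x$q, x$rr, x$n))
  invisible(x)
}
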