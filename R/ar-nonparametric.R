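# Per-subject Kaplan-Meier martingale terms.  For the KM estimate built from
# (time, event) with event-time table `tab`, subject i contributes
#   h_i(t) = event_i 1(time_i <= t) / Y(time_i) - sum_{u_j <= min(time_i, t)} dN_j / Y_j^2
# and the iid representation is  S_hat(t) - S(t) ~ -S_hat(t) * sum_i h_i(t).
km_h <- function(time, event, tab, t) {
  if (!length(tab$u)) return(numeric(length(time)))
  cc <- cumsum(tab$dN / tab$Y^2)
  pos <- findInterval(pmin(time, t), tab$u)
  h <- -c(0, cc)[pos + 1L]
  ev <- event == 1L & time <= t
  if (any(ev))
    h[ev] <- h[ev] + 1 / tab$Y[match(time[ev], tab$u)]
  h
}

# Step evaluation of the survival value implied by a km_table at time t.
km_tab_eval <- function(tab, t) c(1, tab$surv)[findInterval(t, tab$u) + 1L]

#' Nonparametric attributable risk estimation (KM and WKM)
#'
#' Estimates the time-dependent attributable risk
#' \deqn{\hat A(t) = 1 - \frac{1 - \hat S_0(t)}{1 - \hat S(t)}}
#' with \eqn{\hat S_0} the Kaplan-Meier curve of the baseline stratum
#' (stratum coded 0, the unexposed under the default stratification) and
#' \eqn{\hat S} either the pooled Kaplan-Meier curve (`weighting = "km"`) or
#' the stratum-size-weighted Kaplan-Meier average (`weighting = "wkm"`).
#'
#' Standard errors come, by default, from the counting-process
#' influence-function representation of \eqn{\hat A(t)} (the same
#' large-sample route as classical Kaplan-Meier variance theory, accounting
#' for the correlation between \eqn{\hat S_0} and \eqn{\hat S} induced by
#' the shared baseline subjects); a subject-level nonparametric bootstrap is
#' available behind the same interface as a cross-check.
#'
#' Times before the first pooled event have \eqn{1 - \hat S(t) = 0}, so
#' \eqn{\hat A(t)} is undefined there and reported as `NA` (other times are
#' still returned).
#'
#' @param sample a [cohort_sample()]; must contain baseline (stratum 0)
#'   subjects.
#' @param times evaluation times (years), > 0.
#' @param weighting `"km"` (pooled Kaplan-Meier for \eqn{\hat S}) or
#'   `"wkm"` (weighted Kaplan-Meier).
#' @param variance `"if"` (influence function, default), `"bootstrap"`, or
#'   `"none"`.
#' @param boot_reps bootstrap replicates when `variance = "bootstrap"`.
#' @param seed optional RNG seed for the bootstrap.
#' @param conf_level nominal confidence level for Wald intervals.
#' @param transform CI scale, `"identity"` or `"cloglog"` (built on
#'   \eqn{\ln\{1 - A(t)\}}).
#' @return An [ar_curve()].
#' @examples
#' cfg <- scenario_config(model = "ph", n = 400, seed = 7)
#' s <- simulate_cohort(cfg)
#' ar_nonparametric(s, times = c(5, 10, 15, 20))
#' @export
ar_nonparametric <- function(sample, times,
                             weighting = c("km", "wkm"),
                             variance = c("if", "bootstrap", "none"),
                             boot_reps = 200, seed = NULL,
                             conf_level = 0.95,
                             transform = c("identity", "cloglog")) {
  stopifnot(inherits(sample, "cohort_sample"))
  weighting <- match.arg(weighting)
  variance <- match.arg(variance)
  transform <- match.arg(transform)
  if (any(times <= 0)) stop("evaluation times must be positive")
  if (!any(sample$stratum == 0L))
    stop("no baseline (stratum 0) subjects; A(t) is undefined")

  n <- nrow(sample)
  i0 <- sample$stratum == 0L
  tab0 <- km_table(sample$time[i0], sample$event[i0])

  strata <- sort(unique(sample$stratum))
  if (weighting == "km") {
    tabP <- km_table(sample$time, sample$event)
  } else {
    tabs <- lapply(strata, function(k) {
      ik <- sample$stratum == k
      km_table(sample$time[ik], sample$event[ik])
    })
    nk <- vapply(strata, function(k) sum(sample$stratum == k), integer(1))
    kidx <- match(sample$stratum, strata)
  }

  point <- function(t) {
    S0 <- km_tab_eval(tab0, t)
    S <- if (weighting == "km") km_tab_eval(tabP, t) else
      sum(vapply(seq_along(strata),
                 function(i) nk[i] * km_tab_eval(tabs[[i]], t),
                 numeric(1))) / n
    c(S0 = S0, S = S)
  }

  est <- se <- rep(NA_real_, length(times))
  for (m in seq_along(times)) {
    t <- times[m]
    p <- point(t)
    S0 <- p[["S0"]]; S <- p[["S"]]
    FF <- 1 - S
    if (FF <= 0) next  # no events yet: A(t) undefined
    est[m] <- 1 - (1 - S0) / FF
    if (variance == "if") {
      a <- 1 / FF
      b <- (1 - S0) / FF^2
      s0c <- numeric(n)
      s0c[i0] <- -n * S0 * km_h(sample$time[i0], sample$event[i0], tab0, t)
      if (weighting == "km") {
        sc <- -n * S * km_h(sample$time, sample$event, tabP, t)
      } else {
        sc <- numeric(n)
        for (i in seq_along(strata)) {
          ik <- sample$stratum == strata[i]
          Sk <- km_tab_eval(tabs[[i]], t)
          sc[ik] <- (Sk - S) -
            Sk * nk[i] * km_h(sample$time[ik], sample$event[ik], tabs[[i]], t)
        }
      }
      phi <- a * s0c - b * sc
      se[m] <- sqrt(sum(phi^2)) / n
    }
  }
  if (anyNA(est))
    warning("A(t) undefined (no events yet) at time(s): ",
            paste(times[is.na(est)], collapse = ", "))

  if (variance == "bootstrap") {
    se <- boot_se(sample, times, boot_reps, seed, function(s, tt) {
      as.numeric(ar_nonparametric(s, tt, weighting = weighting,
                                  variance = "none")$estimate)
    })
  }

  ci <- wald_ci(est, se, level = conf_level, transform = transform)
  ar_curve(toupper(weighting), times, est, se, ci$lower, ci$upper,
           conf_level = conf_level, transform = transform, n = n)
}

# Subject-level nonparametric bootstrap of a time-indexed estimator.
# `statistic(sample, times)` must return one estimate per time.
boot_se <- function(sample, times, boot_reps, seed, statistic) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sample)
  reps <- matrix(NA_real_, boot_reps, length(times))
  for (b in seq_len(boot_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    bs <- cohort_sample(sample$time[idx], sample$event[idx],
                        sample$exposure[idx], sample$stratum[idx])
    reps[b, ] <- tryCatch(suppressWarnings(statistic(bs, times)),
                          error = function(e) rep(NA_real_, length(times)))
  }
  apply(reps, 2, sd, na.rm = TRUE)
}
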