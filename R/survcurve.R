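#' Survival curve objects
#'
#' A `survcurve` is a right-continuous step estimate of a survival function:
#' sorted distinct event (jump) times, the survival probability at each jump,
#' and the convention that the curve equals 1 before the first jump.
#' Evaluation at an arbitrary time uses the value at the closest preceding
#' jump time.
#'
#' @param time sorted distinct jump times.
#' @param surv survival probabilities at the jump times (nonincreasing,
#'   within \[0, 1\]).
#' @param n.risk,n.event optional risk-set sizes and event counts at the
#'   jump times (kept for variance computations).
#' @param n number of subjects the curve was estimated from.
#' @param label short description.
#' @return An object of class `"survcurve"`.
#' @export
survcurve <- function(time, surv, n.risk = NULL, n.event = NULL,
                      n = NA_integer_, label = "") {
  if (is.unsorted(time, strictly = TRUE))
    stop("jump times must be sorted and distinct")
  if (length(surv) != length(time))
    stop("time and surv must have equal length")
  if (any(surv < -1e-12 | surv > 1 + 1e-12))
    stop("survival values must lie in [0, 1]")
  if (any(diff(surv) > 1e-12))
    stop("survival values must be nonincreasing")
  structure(list(time = time, surv = pmin(pmax(surv, 0), 1),
                 n.risk = n.risk, n.event = n.event,
                 n = as.integer(n), label = label),
            class = "survcurve")
}

#' @export
print.survcurve <- function(x, ...) {
  cat(sprintf("Survival curve%s: %d jump times, n = %d\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              length(x$time), x$n))
  if (length(x$time)) {
    idx <- unique(round(seq(1, length(x$time), length.out = min(6, length(x$time)))))
    print(data.frame(time = x$time[idx], surv = round(x$surv[idx], 4)),
          row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate a survival curve
#'
#' Right-continuous step evaluation: \eqn{\hat S(t)} is the value at the
#' closest preceding jump time, and 1 before the first jump.
#'
#' @param curve a [survcurve()].
#' @param t times at which to evaluate (vectorized).
#' @return Numeric vector of survival probabilities.
#' @export
eval_surv <- function(curve, t) {
  stopifnot(inherits(curve, "survcurve"))
  if (any(t < 0)) stop("evaluation times must be nonnegative")
  idx <- findInterval(t, curve$time)
  c(1, curve$surv)[idx + 1L]
}

# Event-time table used by Kaplan-Meier estimation and by the
# influence-function variance: distinct event times u, risk-set sizes Y(u)
# (subjects with observed time >= u) and event counts dN(u).  Events precede
# censorings at tied times, which the >= risk-set definition encodes.
km_table <- function(time, event) {
  u <- sort(unique(time[event == 1L]))
  if (!length(u))
    return(list(u = numeric(0), Y = integer(0), dN = integer(0),
                surv = numeric(0)))
  st <- sort(time)
  Y <- length(time) - findInterval(u, st, left.open = TRUE)
  dN <- tabulate(match(time[event == 1L], u), nbins = length(u))
  surv <- cumprod(1 - dN / Y)
  list(u = u, Y = Y, dN = dN, surv = surv)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function, optionally restricted
#' to one stratum of the sample.  Delegates the product-limit computation to
#' [survival::survfit()].
#'
#' @param sample a [cohort_sample()].
#' @param restrict_stratum optional integer; if given, only subjects with
#'   this stratum label enter the estimate.
#' @return A [survcurve()] with jump times at the distinct observed event
#'   times.
#' @examples
#' s <- cohort_sample(c(1, 2, 3), c(1, 1, 1), c(0, 0, 0))
#' eval_surv(km_survival(s), 1.5)  # 2/3
#' @export
km_survival <- function(sample, restrict_stratum = NULL) {
  stopifnot(inherits(sample, "cohort_sample"))
  lab <- "pooled"
  if (!is.null(restrict_stratum)) {
    keep <- sample$stratum == restrict_stratum
    if (!any(keep))
      stop("stratum ", restrict_stratum, " has no subjects")
    sample <- sample[keep, , drop = FALSE]
    lab <- paste0("stratum ", restrict_stratum)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = as.data.frame(sample))
  keep <- fit$n.event > 0
  survcurve(time = fit$time[keep], surv = fit$surv[keep],
            n.risk = fit$n.risk[keep], n.event = fit$n.event[keep],
            n = nrow(sample), label = paste0("KM, ", lab))
}

#' Weighted Kaplan-Meier survival estimate
#'
#' Stratum-size-weighted average of per-stratum Kaplan-Meier curves,
#' \deqn{\hat S(t) = \frac{1}{n} \sum_{k=0}^K n_k \hat S_k(t),}
#' where \eqn{\hat S_k} is the Kaplan-Meier estimate within covariate
#' profile \eqn{k} and \eqn{n_k} the stratum size.  With a single stratum it
#' reduces to [km_survival()].
#'
#' @param sample a [cohort_sample()]; every stratum must be nonempty (which
#'   the [cohort_sample()] contiguity invariant guarantees).
#' @return A [survcurve()] whose jump set is the union of the stratum jump
#'   sets.
#' @export
wkm_survival <- function(sample) {
  stopifnot(inherits(sample, "cohort_sample"))
  strata <- sort(unique(sample$stratum))
  curves <- lapply(strata, function(k) km_survival(sample, k))
  nk <- vapply(strata, function(k) sum(sample$stratum == k), integer(1))
  u <- sort(unique(unlist(lapply(curves, `[[`, "time"))))
  if (!length(u))
    return(survcurve(numeric(0), numeric(0), n = nrow(sample),
                     label = "WKM"))
  vals <- vapply(seq_along(strata),
                 function(i) eval_surv(curves[[i]], u), numeric(length(u)))
  surv <- as.numeric(matrix(vals, nrow = length(u)) %*% nk) / nrow(sample)
  survcurve(time = u, surv = surv, n = nrow(sample), label = "WKM")
}
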