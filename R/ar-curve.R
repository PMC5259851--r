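#' Attributable risk curve objects
#'
#' An `ar_curve` collects estimates of the time-dependent attributable risk
#' \eqn{\hat A(t)} at requested times, together with standard errors and
#' Wald confidence limits, tagged by estimation method.  Estimates can be
#' negative (early sampling noise) but never exceed 1; times with no events
#' yet observed have an undefined \eqn{\hat A(t)} and are reported as `NA`.
#'
#' @param method method label (e.g. `"KM"`, `"WKM"`, `"COX"`, `"PCH"`).
#' @param time evaluation times (years).
#' @param estimate attributable risk estimates.
#' @param se standard errors (may be `NA` when no variance was requested).
#' @param ci_low,ci_high confidence limits.
#' @param conf_level nominal confidence level.
#' @param transform CI transform used, `"identity"` or `"cloglog"`.
#' @param n sample size the curve was estimated from.
#' @return A `data.frame` of class `"ar_curve"` with columns
#'   `method`, `time`, `estimate`, `se`, `ci_low`, `ci_high`.
#' @export
ar_curve <- function(method, time, estimate, se = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_,
                     conf_level = 0.95, transform = "identity",
                     n = NA_integer_) {
  m <- length(time)
  out <- data.frame(method = rep_len(method, m), time = time,
                    estimate = estimate,
                    se = rep_len(se, m),
                    ci_low = rep_len(ci_low, m),
                    ci_high = rep_len(ci_high, m))
  ok <- !is.na(out$estimate)
  if (any(out$estimate[ok] > 1 + 1e-8))
    stop("attributable risk estimates cannot exceed 1")
  both <- ok & !is.na(out$ci_low) & !is.na(out$ci_high)
  if (any(out$ci_low[both] > out$estimate[both] + 1e-8) ||
      any(out$ci_high[both] < out$estimate[both] - 1e-8))
    stop("confidence limits must bracket the estimate")
  attr(out, "conf_level") <- conf_level
  attr(out, "transform") <- transform
  attr(out, "n") <- as.integer(n)
  class(out) <- c("ar_curve", "data.frame")
  out
}

#' @export
print.ar_curve <- function(x, digits = 4, ...) {
  cat(sprintf("Attributable risk curve [%s], n = %s, %d%% CI (%s scale)\n",
              x$method[1], attr(x, "n"),
              round(100 * attr(x, "conf_level")), attr(x, "transform")))
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits = digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write / read an attributable risk curve as CSV
#'
#' Columns: `method,time,estimate,se,ci_low,ci_high`.
#'
#' @param curve an [ar_curve()].
#' @param path file path.
#' @return `path` (write) or an `ar_curve` (read).
#' @export
write_ar_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ar_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ar_curve
#' @export
read_ar_curve <- function(path) {
  df <- read.csv(path, header = TRUE)
  need <- c("method", "time", "estimate", "se", "ci_low", "ci_high")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  ar_curve(df$method, df$time, df$estimate, df$se, df$ci_low, df$ci_high)
}
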