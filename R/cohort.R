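#' Construct a cohort sample
#'
#' A cohort sample holds one record per subject: the observed follow-up time
#' (in years), the event indicator (1 = event observed, 0 = right-censored),
#' a binary exposure code, and an integer stratum label used by the weighted
#' Kaplan-Meier estimator.  By default the stratum is the exposure itself,
#' which is the setting of a single binary risk factor.
#'
#' @param time nonnegative follow-up times (years).
#' @param event event indicators, coded 0/1.
#' @param exposure binary exposure codes, 0 = unexposed, 1 = exposed.
#' @param stratum integer covariate-profile labels forming a contiguous
#'   `0..K` set; defaults to `exposure`.
#' @return A `data.frame` of class `"cohort_sample"` with columns
#'   `time`, `event`, `exposure`, `stratum`.
#' @examples
#' cohort_sample(time = c(1, 2, 3), event = c(1, 0, 1), exposure = c(0, 1, 0))
#' @export
cohort_sample <- function(time, event, exposure, stratum = exposure) {
  time <- as.numeric(time)
  event <- as.integer(event)
  exposure <- as.integer(exposure)
  stratum <- as.integer(stratum)
  n <- length(time)
  if (n < 1L) stop("a cohort sample needs at least one record")
  if (length(event) != n || length(exposure) != n || length(stratum) != n)
    stop("time, event, exposure and stratum must have equal length")
  if (anyNA(time) || anyNA(event) || anyNA(exposure) || anyNA(stratum))
    stop("missing values are not allowed in a cohort sample")
  bad <- which(time < 0 | !is.finite(time))
  if (length(bad))
    stop("negative or non-finite follow-up times at rows: ",
         paste(head(bad, 5L), collapse = ", "))
  bad <- which(!event %in% c(0L, 1L))
  if (length(bad))
    stop("event must be coded 0/1; offending rows: ",
         paste(head(bad, 5L), collapse = ", "))
  bad <- which(!exposure %in% c(0L, 1L))
  if (length(bad))
    stop("exposure must be coded 0/1; offending rows: ",
         paste(head(bad, 5L), collapse = ", "))
  lev <- sort(unique(stratum))
  if (!identical(lev, seq(0L, max(lev))))
    stop("stratum labels must form a contiguous 0..K set; found: ",
         paste(lev, collapse = ", "))
  out <- data.frame(time = time, event = event,
                    exposure = exposure, stratum = stratum)
  class(out) <- c("cohort_sample", "data.frame")
  out
}

#' @export
print.cohort_sample <- function(x, ...) {
  cat(sprintf(
    "Cohort sample: %d subjects, %d events (%.1f%%), %d exposed (%.1f%%), %d strata\n",
    nrow(x), sum(x$event), 100 * mean(x$event),
    sum(x$exposure), 100 * mean(x$exposure), length(unique(x$stratum))))
  cat(sprintf("Follow-up range: %.3g to %.3g years\n",
              min(x$time), max(x$time)))
  invisible(x)
}

#' Read a cohort sample from a CSV file
#'
#' Expects a header row and columns `time`, `event`, `exposure` and
#' optionally `stratum` (comma separated, period decimal).  Validation
#' failures are reported with the offending data row numbers.
#'
#' @param path path to a CSV file.
#' @return A [cohort_sample()].
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, header = TRUE)
  need <- c("time", "event", "exposure")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in c("event", "exposure")) {
    v <- df[[col]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad))
      stop(sprintf("column '%s' must be coded 0/1; offending row(s): %s",
                   col, paste(head(bad, 5L), collapse = ", ")))
  }
  bad <- which(is.na(df$time) | df$time < 0)
  if (length(bad))
    stop("column 'time' must be nonnegative; offending row(s): ",
         paste(head(bad, 5L), collapse = ", "))
  if (is.null(df$stratum)) df$stratum <- df$exposure
  cohort_sample(df$time, df$event, df$exposure, df$stratum)
}

#' Write a cohort sample to a CSV file
#'
#' @param sample a [cohort_sample()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(sample, path) {
  stopifnot(inherits(sample, "cohort_sample"))
  write.csv(as.data.frame(sample), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply administrative censoring to a cohort sample
#'
#' Truncates follow-up at `at` years: any subject still under observation is
#' censored there.  Used to compare estimators on shortened follow-up.
#'
#' @param sample a [cohort_sample()].
#' @param at administrative censoring time (years), > 0.
#' @return A [cohort_sample()] with truncated follow-up.
#' @export
censor_cohort <- function(sample, at) {
  stopifnot(inherits(sample, "cohort_sample"), is.numeric(at), at > 0)
  event <- ifelse(sample$time > at, 0L, sample$event)
  time <- pmin(sample$time, at)
  cohort_sample(time, event, sample$exposure, sample$stratum)
}
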