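#' Write small deterministic example datasets
#'
#' Three fixture kinds, used by the tests and documentation:
#' * `"toy"` — a fixed, hand-checkable 10-subject cohort together with the
#'   hand-computed Kaplan-Meier values of its pooled curve;
#' * `"table1"` — one replicate of the constant-baseline-hazard PH scenario
#'   (\eqn{\gamma = 1}, \eqn{\beta = \ln 2}, \eqn{q = 0.5}, n = 1000) with
#'   its closed-form truth table;
#' * `"nph"` — one replicate of the nonproportional-hazards scenario
#'   (\eqn{\lambda_0 = 0.1}) with its truth table.
#'
#' @param kind `"toy"`, `"table1"` or `"nph"`.
#' @param dir output directory (created if missing).
#' @param seed RNG seed for the simulated kinds.
#' @return Character vector of the files written.
#' @export
make_fixture <- function(kind = c("toy", "table1", "nph"), dir = ".",
                         seed = 20260101) {
  kind <- match.arg(kind)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  if (kind == "toy") {
    # events at 1, 3, 5, 7, 9; censorings interleaved; hand product-limit:
    # S(1) = 9/10, S(3) = 9/10 * 7/8, ...
    smp <- cohort_sample(
      time = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
      event = c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0),
      exposure = c(1, 0, 1, 0, 1, 0, 0, 1, 0, 1))
    f1 <- file.path(dir, "toy_cohort.csv")
    write_cohort_csv(smp, f1)
    km <- km_survival(smp)
    f2 <- file.path(dir, "toy_km_expected.csv")
    write.csv(data.frame(time = km$time, surv = km$surv), f2,
              row.names = FALSE, quote = FALSE)
    files <- c(f1, f2)
  } else {
    cfg <- if (kind == "table1")
      scenario_config(model = "ph", gamma = 1, n = 1000, seed = seed)
    else
      scenario_config(model = "nph", n = 1000, seed = seed)
    smp <- simulate_cohort(cfg, seed = seed)
    f1 <- file.path(dir, paste0(kind, "_cohort.csv"))
    write_cohort_csv(smp, f1)
    tt <- cfg$tau * (1:4) / 4
    f2 <- file.path(dir, paste0(kind, "_truth.csv"))
    write.csv(data.frame(time = tt,
                         true_ar = theoretical_ar(cfg, tt),
                         true_global_ar = theoretical_global_ar(cfg)),
              f2, row.names = FALSE, quote = FALSE)
    files <- c(f1, f2)
  }
  invisible(files)
}
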