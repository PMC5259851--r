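# Shared fixtures, all generated in code.

# One replicate of the constant-baseline-hazard PH scenario.
ph_sample <- function(n = 1000, seed = 1, gamma = 1, beta = log(2),
                      q = 0.5) {
  cfg <- scenario_config(model = "ph", gamma = gamma, beta = beta, q = q,
                         n = n, seed = seed)
  simulate_cohort(cfg)
}

nph_sample <- function(n = 1000, seed = 1) {
  simulate_cohort(scenario_config(model = "nph", n = n, seed = seed))
}

# A deterministic sample whose two exposure arms have identical times and
# event patterns, so the true and fitted exposure effect is exactly null.
null_effect_sample <- function() {
  times <- c(1, 2, 3, 4, 5, 6, 7, 8)
  events <- c(1, 1, 0, 1, 1, 0, 1, 0)
  cohort_sample(time = rep(times, 2), event = rep(events, 2),
                exposure = rep(c(0, 1), each = length(times)))
}

# Independent product-limit oracle: straight loop over the textbook
# definition, no shared code with the package internals.
product_limit <- function(time, event, t) {
  u <- sort(unique(time[event == 1]))
  s <- 1
  for (v in u[u <= t]) {
    atrisk <- sum(time >= v)
    d <- sum(time == v & event == 1)
    s <- s * (1 - d / atrisk)
  }
  s
}
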