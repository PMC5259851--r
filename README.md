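# paftime

Attributable risk estimation over time from censored cohort data.

## What this package is for

Epidemiologists quantify the population impact of an exposure with the
attributable risk (AR, also called the population attributable
fraction): the proportion of disease cases attributable to the
exposure.  In a cohort study with right-censored time-to-event
outcomes, the AR is naturally a *function of time*.  Interpreting
disease probability by time *t* through cumulative distribution
functions gives

```
A(t) = 1 - (1 - S0(t)) / (1 - S(t))
```

where `S(t)` is the survival function of the population as observed
and `S0(t)` the counterfactual survival function with exposure removed.
`paftime` implements, for a binary exposure, the four established
estimators of `A(t)` together with single-number global estimators:

| function | method | S0 / S estimated by |
|---|---|---|
| `ar_nonparametric(..., weighting = "km")` | KM | Kaplan-Meier (unexposed / pooled) |
| `ar_nonparametric(..., weighting = "wkm")` | WKM | Kaplan-Meier / stratum-weighted Kaplan-Meier |
| `ar_cox()` | COX | Cox model, Breslow baseline cumulative hazard |
| `ar_pch()` | PCH | piecewise constant hazards ML fit, delta-method SEs |
| `simpler_ar()`, `global_ar_from_cohort()` | global | `q(RR-1)/(1+q(RR-1))` with Cox hazard ratio |

It also ships the machinery needed to *validate* such estimators: a
seedable cohort simulator (Weibull proportional hazards with constant,
increasing or decreasing baseline hazard; a nonproportional-hazards
transformation model whose hazard ratio decays from 2 toward 1;
uniform censoring), closed-form truth `theoretical_ar()`, and a Monte
Carlo harness `run_scenario()` reporting bias, mean estimated standard
error (SEE), empirical standard deviation (SSD) and 95% CI coverage.

The methods vignette
(`vignettes/attributable-risk-over-time.Rmd`) documents the models,
the variance estimators (influence-function / delta-method defaults
with a bootstrap cross-check), numerical conventions and limitations.

## Worked example

Simulate one cohort under proportional hazards (constant baseline
hazard, hazard ratio 2, 50% exposed, 15-year unexposed median survival,
uniform censoring over 20 years) and estimate `A(t)`:

```r
library(paftime)

cfg <- scenario_config(model = "ph", gamma = 1, n = 2000, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> Cohort sample: 2000 subjects, 904 events (45.2%), 977 exposed (48.9%), 2 strata
#> Follow-up range: 0.00183 to 20 years

round(theoretical_ar(cfg, c(5, 10, 15, 20)), 3)   # closed-form truth
#> [1] 0.284 0.240 0.200 0.166

ar_nonparametric(cohort, times = c(5, 10, 15, 20))
#> Attributable risk curve [KM], n = 2000, 95% CI (identity scale)
#>  method time estimate     se ci_low ci_high
#>      KM    5   0.2831 0.0356 0.2134  0.3529
#>      KM   10   0.2467 0.0263 0.1952  0.2982
#>      KM   15   0.2210 0.0241 0.1737  0.2683
#>      KM   20   0.1899 0.0290 0.1330  0.2468

ar_cox(cohort, times = c(5, 10, 15, 20))
#> Attributable risk curve [COX], n = 2000, 95% CI (identity scale)
#>  method time estimate     se ci_low ci_high
#>     COX    5   0.2893 0.0267 0.2369  0.3417
#>     COX   10   0.2402 0.0230 0.1951  0.2853
#>     COX   15   0.2041 0.0201 0.1646  0.2435
#>     COX   20   0.1704 0.0184 0.1342  0.2065

global_ar_from_cohort(cohort)
#> Global attributable risk (baseline prevalence): 0.3417 (SE 0.0303)
#> 95% CI: 0.2823 to 0.4011
#> q = 0.4885, RR = 2.0625, n = 2000
```

Reading the numbers: about 28% of the events occurring by year 5 are
attributable to the exposure, declining to about 17% by year 20 (the
exposed fail earlier, so the exposed share of the still-event-free
population shrinks).  Each estimate comes with a standard error —
influence-function based for KM/WKM/COX, delta-method for PCH — and a
Wald interval covering the closed-form truth.  The single-number
global estimate (0.34 here) exceeds the time-dependent values at every
interior time because it freezes the exposure prevalence at baseline.

A Monte Carlo comparison of all methods under a chosen scenario is one
call:

```r
run_scenario(scenario_config(model = "nph", n = 1000, reps = 500, seed = 1),
             methods = c("km", "cox", "pch"))
```

Under that nonproportional-hazards model the KM rows stay unbiased
while the COX and PCH rows show the bias (~ +0.03 at year 20) and
collapsed coverage that motivate checking the proportional hazards
assumption before trusting PH-based AR estimates.

A thin command-line wrapper is installed at `inst/cli/paftime` with
`simulate`, `estimate`, `evaluate` and `fixtures` subcommands; every
subcommand takes `--seed` and writes a JSON run manifest next to its
outputs.

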