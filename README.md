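# updrsdyn

Quantifying short-term (days-to-weeks) dynamics in longitudinal,
self-reported Parkinson's disease symptom scores.

High-frequency self-report platforms let patients score themselves on
UPDRS Parts I (mentation/behavior/mood, 4 items) and II (activities of
daily living, 13 items) every few weeks — each report an integer total in
[0, 68]. Clinic-based datasets sample months apart, so the fluctuation of
symptoms *around* the progression trend has historically been invisible.
`updrsdyn` measures it:

1. **Inclusion filter** — keep patients with at least 15 reports and a
   mean reporting interval of at most 65 days.
2. **Trend estimation** — per patient, solve the convex program

   minimize ½ Σᵢ (yᵢ − xᵢ)² + λ Σᵢ |slope change at tᵢ|,

   i.e. least squares penalized by the total variation of the discrete
   slope on the irregular time grid. Solutions are piecewise linear with
   knots at data points; λ is chosen per patient by 5-fold
   cross-validation on a log grid anchored at the closed-form λ_max (the
   smallest λ whose fit is the OLS line). Knots flag abrupt changes in
   progression; robust residual screening flags single outlier reports.
3. **Fluctuation model** — pool detrended residuals r across patients and
   fit a gamma GLM with log link, E[|r| given t] = exp(β₀ + β₁ t), where t
   is years since diagnosis; report predictions with Wald intervals,
   a bootstrap test of residual skewness, and comparisons against
   clinically important differences (CIDs) scaled from the 0–176 total
   UPDRS to the 0–68 subscale by 68/176 (minimal 4.3 → 1.7 points,
   moderate 8.5 → 3.3 points).
4. **Distribution validation** — z-scored two-sample Kolmogorov–Smirnov
   tests and quantile–quantile pairing for comparing a self-report cohort
   against a clinical reference sample.
5. **Synthetic cohorts** — a seeded generator emulating the structure of
   such data (reporting cadence, smooth/plateau/abrupt-change/outlier
   trend archetypes, zero-mean positively skewed residuals whose mean
   absolute value grows exponentially in t) with full ground truth, used
   throughout the tests for parameter-recovery verification.

See the methods vignette (`vignettes/updrs-short-term-dynamics.Rmd`) for
the model details, numerical choices, and limitations.

## A worked example

```r
library(updrsdyn)
report <- run_pipeline(run_config(seed = 1))
print(report)
#> <run_report> 100 patients, 3022 reports
#>   fluctuation: E|r| = exp(0.8825 + 0.0393 t)
#>   predicted mean |residual|: 2.4 pts at t = 0, 4.5 pts at t = 16
#>   skewness 1.286 (bootstrap p = 1.51e-45)

report$fluctuation$predictions
#>    t  mean ci_low ci_high
#> 1  0 2.417  2.242   2.606
#> 2 16 4.535  3.363   6.117
```

Reading the output: on this simulated 100-patient cohort the pipeline
estimates that a patient's self-reported score fluctuates around their
progression trend by about 2.4 points (mean absolute residual) at the
time of diagnosis, growing to about 4.5 points 16 years later (the latter
an extrapolation beyond the cohort's observation window — note the wide
interval). Both exceed the scaled minimal CID of 1.7 points
(`report$cid`), so short-term fluctuation alone is large enough to be
mistaken for a clinically meaningful change. The pooled residuals are
strongly positively skewed (skewness 1.29), confirming the fluctuation is
not a symmetric-noise artifact of the bounded scale. The per-patient
trend diagnostics (`report$patients`) list each λ\*, knot times, abrupt
slope changes and outlier reports.

Individual stages are exposed directly (`simulate_cohort()`,
`apply_inclusion_filter()`, `fit_trend()`, `fit_trend_cv()`,
`fit_gamma_glm()`, `bootstrap_skewness_test()`, `ks_two_sample()`,
`scale_cid()`, ...), and a thin command-line interface with
`simulate` / `filter` / `validate` / `trend` / `fluctuation` / `run-all`
subcommands lives at `inst/cli/updrsdyn.R`.

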