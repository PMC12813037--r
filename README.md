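# hrvfda

Functional data analysis of 24-hour high-frequency heart-rate-variability
(HF-HRV) profiles from multi-day ambulatory RR-interval recordings, for
studies relating cardiac vagal control to cognitive status in older
adults.

Long ambulatory ECG recordings are usually collapsed to one summary number
per person, discarding the time-of-day structure of vagal tone. `hrvfda`
instead treats each person's day as a function: HF band power
(0.15–0.40 Hz, ms²) is computed on 5-minute clock-aligned epochs, log
transformed, filtered by epoch- and day-level validity rules, and averaged
across valid days into a 288-bin profile $Y_i(t)$. Profiles are related to
scalar covariates through a function-on-scalar additive mixed model

$$Y_i(t) = \beta_0(t) + \textstyle\sum_k \beta_k(t)\,x_{ik} + b_i + \varepsilon_i(t)$$

with penalized cyclic-spline coefficient curves $\beta_k(t)$, a subject
random intercept $b_i \sim N(0,\sigma_b^2)$, REML-selected smoothing,
pointwise 95% bands, clock-time significance windows, and standardized
effect sizes. Cognitive status (MCI vs CN) is assigned by the Jak/Bondi
actuarial criteria from normed neuropsychological z-scores. A calibrated
synthetic-data generator supplies cohorts, RR recordings, and epoch-level
outcomes with known ground truth.

## A worked example

```r
library(hrvfda)

cfg <- generator_config(n_subjects = 81, seed = 42)   # calibrated defaults
res <- run_pipeline(cfg, path = "rr")                 # full signal path

mean(res$exclusions$n_valid_days)
#> [1] 6.703704
round(c(mean(res$person_means$mean_ln_hf), sd(res$person_means$mean_ln_hf)), 2)
#> [1] 4.42 0.76
sum(res$classification$mci)
#> [1] 20
significance_windows(res$fit, "mci")
#> # A tibble: 1 × 6
#>   start_hour end_hour start_clock end_clock sign  n_bins
#>        <dbl>    <dbl> <chr>       <chr>     <chr>  <int>
#> 1       22.8     1.33 22:50       01:20     below     30
```

The simulated cohort keeps ~6.6 of 8 recorded days after the
100-valid-epoch day rule, person-level mean Ln(HF-HRV) ≈ 4.5 ± 0.8 ln ms²,
and 20/81 subjects classified MCI; the fitted MCI coefficient curve is
significantly below zero overnight, where its true nocturnal dip (depth
0.6 ln ms² at midnight) lies. `plot_profiles()` and `plot_coefficients()`
draw the per-subject profile spaghetti and the coefficient curves with
their shaded pointwise bands; `summarize_cohort()` renders the stratified
descriptive table with rank-sum / chi-squared / Fisher comparisons.

A thin command-line wrapper over the same functions ships in
`inst/cli/hrvfda` (`simulate`, `preprocess`, `profiles`, `classify`,
`fit`, `run`).

## Package layout

| Path | Contents |
|---|---|
| `R/synth.R` | generator config, cohort/truth simulation, RR + direct epoch paths, wear/artifact model |
| `R/rr.R`, `src/rr_kernels.cpp` | artifact flagging/interpolation, clock-aligned segmentation |
| `R/spectra.R` | interval spectrum, HF band power, log transform |
| `R/profiles.R` | day validity, profile averaging, exclusion accounting |
| `R/cognition.R` | Jak/Bondi classifier and domain impairment flags |
| `R/fosr.R` | cyclic spline basis/penalty, REML fit, bands, windows, Cohen's d |
| `R/report.R` | person-level means, stratified descriptives, figures |
| `R/pipeline.R` | orchestration and CSV/JSON/YAML IO |
| `vignettes/hrv-circadian-fosr.Rmd` | methods: model, assumptions, calibration, limitations |
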