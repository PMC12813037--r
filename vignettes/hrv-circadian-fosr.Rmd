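---
title: "Modeling 24-hour HF-HRV profiles with function-on-scalar regression"
author: "hrvfda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 24-hour HF-HRV profiles with function-on-scalar regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvfda)
```

## The scientific problem

Heart rate variability (HRV) in the high-frequency band (0.15–0.40 Hz,
HF-HRV) indexes cardiac vagal control. Multi-day ambulatory single-lead ECG
gives a 24-hour *profile* of HF-HRV per person rather than the single
summary number of in-clinic recordings, and the association of vagal tone
with cognitive status may be concentrated at particular times of day —
especially overnight, when behavioral confounders (movement, posture,
stressors) are weakest. `hrvfda` implements the full analysis path from an
RR-interval series to time-of-day-specific group contrasts:

1. artifact flagging/interpolation of the RR series;
2. HF band power per 5-minute clock-aligned epoch by the interval-spectrum
   method, natural-log transformed;
3. epoch- and day-level validity filtering and averaging of valid days into
   one 288-bin profile $Y_i(t)$ per subject;
4. actuarial (Jak/Bondi) MCI classification from normed neuropsychological
   z-scores;
5. the function-on-scalar additive mixed model

$$Y_i(t) = \beta_0(t) + \beta_1(t)\,\mathrm{MCI}_i + \beta_2(t)\,\mathrm{Age}_i
+ \beta_3(t)\,\mathrm{Female}_i + \beta_4(t)\,\mathrm{Black}_i
+ \beta_5(t)\,\mathrm{Other}_i + \beta_6(t)\,\mathrm{Educ}_i + b_i +
\varepsilon_i(t),$$

with smooth coefficient curves $\beta_k(t)$, a scalar subject random
intercept $b_i \sim N(0, \sigma_b^2)$, and white noise
$\varepsilon_i(t) \sim N(0, \sigma_\varepsilon^2)$.

Because no cohort data are distributed with the package, a calibrated
synthetic-data generator provides cohorts with known ground truth; every
quantitative claim below is recomputed by the test suite or the acceptance
script, never asserted from memory.

## RR cleaning and epoch validity

The artifact rule compares each interval with the running median of the
last 5 *accepted* intervals; a relative deviation above 20% flags the beat.
Using only accepted beats in the reference is what makes runs of identical
artifacts detectable — a symmetric rolling median that includes the
corrupted neighbors sees zero deviation inside a run. Flagged runs of up to
3 beats are replaced by the reference ("interpolation when possible");
longer runs are excluded, because interpolating long stretches fabricates
rhythm. Both the 20% threshold and the run cutoff are exposed as arguments.

Beat times are rebuilt cumulatively after interpolation, but only within
contiguous segments (a gap of more than 2 s starts a new segment anchored
at its original clock time). Rebuilding across wear gaps would slide whole
epochs off their clock positions, which matters because epochs are
*clock-aligned*: bin $k$ is the half-open interval $[300k, 300(k+1))$
seconds from local midnight, so a beat at exactly 300 s belongs to bin 1.
Epochs with more than 20% interpolated intervals are excluded (the 20%
boundary itself is retained: exclusion is "more than"); days with fewer
than 100 valid epochs are excluded (exactly 100 is valid), with 200 as the
conventional sensitivity threshold.

## The interval spectrum

HF power is computed from the beat-indexed interval sequence: detrend,
DFT, one-sided power normalized so total power equals the variance of the
sequence (Parseval), and frequencies mapped from cycles/beat to Hz through
the mean interval, $f_j = j/(N\bar r)$. Band power is the *sum* of power
over $0.15 \le f < 0.40$ Hz, in ms², not a density. Defaults are linear
detrending (suppresses low-frequency leakage into the band) and no taper
(keeps the sinusoid identity exact: a modulation of amplitude $A$ carries
band power $A^2/2$, the identity the generator inverts and the tests check
to 2%). A Hann taper is available and power-normalized. Epochs need at
least 32 beats — a numerical guard, not an estimate from any study — and
power at or below $10^{-6}$ ms² marks the epoch invalid rather than
producing $-\infty$ on the log scale.

## The penalized fit

Each coefficient curve is expanded in a cyclic cubic B-spline basis
(24 functions over $[0,24)$ h, built by knot wrapping; the tests verify it
spans the same space as `mgcv::cSplineDes`) with a second-order cyclic
difference penalty. Cyclic bases are the natural choice here: the fitted
curves must be continuous across midnight, which is also where the group
contrast of interest peaks. A non-cyclic mode exists as a sensitivity
switch.

The penalties are handled through their mixed-model representation: the
penalty's null space (constants) enters as fixed effects, the penalized
part as i.i.d. Gaussian coefficients with variance
$\sigma^2_\varepsilon/\lambda_k$, and the subject intercept as one more
i.i.d. component. The restricted likelihood, profiled over the error
variance, is minimized over the log smoothing parameters with `nlminb`
(iteration cap 200); with the error variance profiled out each evaluation
is a single Cholesky factorization of the penalized normal equations, so
the fit is fast and — having no random initialization — bit-reproducible.
With the smoothing parameters forced large the model collapses to a scalar
random-intercept mixed model, and the tests require agreement with a
direct generalized-least-squares oracle to $10^{-4}$ and with `lme4::lmer`
to $10^{-3}$ on constant-effect data; `lme4` and `mgcv` appear only in
tests, as independent reference implementations.

Missing bins are simply absent rows: the model is fit to the observed
(subject, bin) pairs without imputation or per-subject weighting.
Pointwise intervals use the posterior covariance of the penalized fit
(`estimate ± z · SE`, shading-style), with no simultaneous-band or
multiple-testing adjustment — inference is deliberately pointwise.
Significance windows are maximal runs of bins whose interval excludes
zero, merged across the midnight wrap and reported as clock intervals.
Cohen's *d* standardizes a group difference by the sample SD of
person-level mean Ln(HF-HRV).

## What the generator emulates — and what it does not

The generator draws covariates matching the motivating cohort's margins
(age truncated-normal 78.3 (5.2) with minimum 70 years; 81.5% female;
ethnicity 38.3/43.2/18.5%; education 14.9 (3.3) years; diabetes 18.5%,
hypertension 67.9%; depression prevalence 0.15, a field-typical figure for
this age range since no margin is printed), with any joint dependence
between covariates omitted. The functional intercept defaults to a
cosinor with mesor 4.5 ln ms², amplitude 0.7, acrophase 03:00 — vagal tone
peaking overnight. The MCI coefficient curve is a raised-cosine dip
centered at midnight spanning 19:00–07:00 with depth 0.6 ln ms². MCI
status is realized through simulated neuropsychological z-scores that the
Jak/Bondi classifier maps back to the assigned status exactly, so the
classification stage is exercised in-pipeline.

Two generation paths exist by design. The *direct* path draws epoch-level
Ln(HF) straight from the model — model-recovery studies should not pay for
signal-processing error. The *RR* path synthesizes a sinusoidally
modulated tachogram per epoch whose HF power equals the target
($A = \sqrt{2 e^{\text{lnHF}}}$), corrupts a fraction of interval values
(default 2%) by ±45–60% — artifacts are mis-measured values, so detector
timestamps are left untouched and the value/time inconsistency is exactly
what cleaning detects — and exercises the full spectral pipeline, which
recovers the target Ln(HF) within 0.05.

Variance components: the study reports neither $\sigma_b$ nor
$\sigma_\varepsilon$. Recovery and calibration simulations that probe the
*fitter* use $\sigma_b = 0.3$, $\sigma_\varepsilon = 1.0$ ln ms². The
*default* config instead targets the printed between-person spread: with
person-level SD $\approx 0.8$ and the covariate effects
(age −0.02/yr, female +0.15, ethnicity −0.10, education +0.01/yr)
contributing ≈0.02 variance, the subject-intercept SD is set to 0.78 so
that $\sqrt{0.78^2 + 0.02} \approx 0.80$; the mesor 4.5 then yields a
person-level mean within a few hundredths of 4.5 after the small MCI and
covariate mean shifts cancel. The wear model is likewise calibrated
analytically: whole-day dropout 0.175 gives $8 \times 0.825 = 6.6$
expected valid days, and the retention curve (0.93 with a mild
mid-afternoon dip, mean ≈ 0.90) keeps non-dropped days far above the
100-epoch rule.

What the generator does *not* emulate: sleep-stage or activity structure,
day-to-day autocorrelation of wear, covariate-dependent missingness,
non-sinusoidal respiratory modulation, or ectopy with physiological
morphology. Passing recovery tests therefore shows the estimator is
correct *under the stated model*, not that real ambulatory data meet that
model.

## Problem sizes and numerical choices

Simulation studies in the tests and the acceptance script use the sizes
the analysis targets: 81 subjects × 8 days × 288 bins, 50 replicates for
the midnight-recovery study, 10 seeded cohorts for the calibration study,
and smaller cohorts (n = 30–40) for coverage and null-calibration sweeps.
One full-cohort fit takes a few seconds; one RR-path cohort pipeline under
a minute. All randomness flows from a single integer seed through a
deterministic sub-seed derivation, so identical configs are bit-identical.

Numerical details worth knowing: the REML optimizer works on
$\log \lambda$ bounded to $[-20, 30]$; the profiled error variance uses
$n - p_f$ degrees of freedom with $p_f$ the total penalty-null-space
dimension; zero-variance epochs produce zero power exactly; `nlminb`'s
"false convergence" on a flat criterion is accepted (the fit at the
returned iterate is well-defined), while exhausting the iteration cap is
an error.

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(n_subjects = 81, seed = 42)
res <- run_pipeline(cfg, path = "rr")
print(res$summary)
print(res$fit)
significance_windows(res$fit, "mci")
plot_coefficients(res$fit)
```

## Known limitations

The fit is dense-matrix and single-threaded: cohorts beyond a few hundred
subjects × 288 bins would want a sparse backend. The classifier consumes
pre-normed z-scores; normative adjustment is upstream by design. The
artifact model corrupts values independently per beat, so detection
performance on correlated real ectopy is untested. Whether rule 1 of the
actuarial criteria should range over all five domains or only the three
named in its usual statement is ambiguous in the literature; the package
defaults to five with `rule1_domains` as the switch.
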