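---
title: "Methods: wildfire smoke modification of PM-asthma associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wildfire smoke modification of PM-asthma associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Short-term increases in particulate matter (PM) are associated with
asthma exacerbations, but PM from wildfire smoke may not be
toxicologically equivalent to PM from traffic and industry.  A
time-series design can separate the two by asking whether the
association between daily PM and daily asthma emergency/urgent-care
visit counts is *modified* on days when an air-quality agency's hourly
qualifier data flag wildfire smoke.  Because smoke days also have much
higher PM concentrations, a naive comparison confounds effect
modification with possible nonlinearity of the concentration-response;
the design therefore restricts wildfire observations to the
concentration range observed without smoke (the exceedance exclusion
below).

`smokegam` implements that design end to end.  This vignette records the
model, the exposure rules, the numerical choices, what the synthetic
world does and does not emulate, and the decisions taken where more than
one convention exists.

## Count model

Daily visit counts are negative binomial (NB2: Var = mu + mu^2/theta)
with log link:

log E(y_t) = alpha + gamma DOW_t + delta HOL_t + f(t) + zeta T7_t
  [+ rho RH7_t] + sum_j eta_j log(1 + y_(t-j)) + beta1 PM_t
  + beta2 (PM_t x WF_t) + beta3 WF_t + theta' MON_t

* **DOW**: six day-of-week indicators (Sunday reference).
* **HOL**: 17 holiday indicators -- the 10 US federal holidays observed
  in 2013-2018 plus Christmas Eve, New Year's Eve, the day after
  Thanksgiving, Easter, Halloween, Cinco de Mayo and Super Bowl Sunday.
  The count of 17 is fixed by the design; the composition of the list is
  a package choice (the extra seven are the non-federal dates most
  plausibly affecting urgent-care utilisation), configurable in
  principle by editing the calendar module.
* **f(t)**: penalized cubic regression spline of the day index, basis
  size 10 by default (a conventional default; the effective degrees of
  freedom are selected by the data, not a priori).
* **T7**: trailing 7-day mean of daily mean temperature (degrees C);
  sensitivity variants swap in the daily minimum or maximum, or add a
  7-day mean relative humidity.
* **AR terms**: lags 1-10 of visits enter as log(1 + y_(t-j)).  The
  literature is ambiguous between lagged raw counts, lagged log-counts
  and lagged residuals; log(1 + y) is bounded, defined at zero counts,
  and lives on the scale of the linear predictor, so the synthetic
  generator and the fitter share it by construction.  The first 10
  usable days are dropped from fitting (AR warm-up).
* **PM**: patient-count-weighted concentration for one fraction
  (PM2.5, PM10-2.5 or PM10) and lag set (0, 0-2, 0-6), scaled so one
  unit is 5 ug/m3.
* **WF**: tri-state wildfire indicator for the same lag set.
* **MON**: one 0/1 activity indicator per monitor (active at *any* lag
  of the set), absorbing level shifts when monitors enter or leave the
  weighted average.  Indicators that are constant over the fitted rows
  (e.g. a monitor active on every day) are unidentifiable next to the
  intercept and are dropped, with the drop recorded in the fit object;
  any remaining column-rank deficiency is an error that names the
  offending columns.

The two-fraction variant replaces the single PM x WF pair with lag-0
PM2.5 and PM10-2.5, their separate smoke interactions (beta2, beta4) and
a smoke main effect (beta5), plus activity indicators for both
fractions.

## Exposure construction

* **Weighted daily exposure**: sum(w_i x_i)/sum(w_i) over the monitors
  active for that fraction on that day, with the weights (counts of
  patients living within 5 km of each monitor) renormalized daily over
  the active subset; missing when no monitor is active.  Activity is
  handled per fraction and per day: a monitor missing only one fraction
  still contributes the others.
* **Wildfire day**: at least one smoke-affected hour in the qualifier
  data.  Prescribed-burn and wildfire smoke are not distinguished.
* **Lag averages**: the mean over lags {0}, {0..2} or {0..6}; a missing
  day anywhere in the window makes the average missing (the paper trail
  is silent; averaging over fewer days would silently change the
  estimand).  The first max(lag) days are undefined and excluded.
* **Tri-state indicator**: 1 if all lags are wildfire days, 0 if none,
  `WF_EXCLUDED` (-1) for mixtures; mixture observations are dropped from
  any model using that indicator.
* **Exceedance exclusion**: wildfire observations (indicator 1) whose
  lag-averaged PM2.5 strictly exceeds the maximum lag-averaged PM2.5
  over non-wildfire observations (indicator 0) are dropped, separately
  per lag set, keying on PM2.5 only.  Boundary equality retains the day
  ("exceeded" is read strictly).  The threshold is computed after
  tri-state exclusion, i.e. over indicator-0 observations only; whether
  mixed-lag days should inform the threshold is genuinely ambiguous, and
  this choice keeps the threshold on the same observation set the model
  actually contrasts.

## Fitting

The penalized log-likelihood l(beta) - (lambda/2) beta' S beta is
maximized by penalized IRLS (Fisher scoring with NB working weights
mu/(1 + mu/theta), step-halving on penalized-deviance increase, cap 200
iterations, relative tolerance 1e-11 with a coefficient-change fallback
at machine precision).  S is the integrated squared second derivative of
the cubic regression spline, built from the natural-spline continuity
equations in the value parameterization; it is symmetric PSD with
exactly a two-dimensional null space (all linear functions of time).
The basis is centered (sum-to-zero over the fitted rows) against the
intercept and the penalty is rescaled so trace(S) matches the spline
block of X'X, making the smoothing parameter O(1).

* **Smoothness selection**: the working-model restricted-likelihood
  score  ||z - X b||^2_W + lambda b'Sb + log|X'WX + lambda S| -
  rank(S) log lambda  is minimized over log lambda (coarse grid, then
  golden-section refinement, warm-started), falling back to GCV
  n D / (n - edf)^2 when the score is non-finite.  This is the
  performance-iteration approximation to REML; the widely used
  alternative (exact Laplace REML) differs negligibly at these sample
  sizes, and the package's selection agrees closely with `mgcv` on the
  same designs (fitted-value correlation > 0.9999 in the test suite's
  cross-check).
* **Dispersion**: theta is estimated by 1-D maximum likelihood given the
  fitted means, alternating with lambda selection until the relative
  deviance change is below 1e-8 (at most 6 rounds).
* **Covariance**: the inverse penalized information
  (X'WX + lambda S)^(-1), the Bayesian-style covariance that underlies
  mgcv-type Wald intervals; all derived quantities use w' Sigma w.
* **Spline EDF convention**: the reported `spline_edf` counts the smooth
  including its straight-line limit as 2 (level + slope), i.e.
  1 + trace of the hat sub-matrix over the centered spline columns.  So
  `spline_edf -> 2` as lambda -> infinity and equals the basis size at
  lambda = 0.  (The alternative convention -- trace over the centered
  columns only, range [1, basis-1] -- is what `mgcv` prints; the two
  differ by exactly 1.)

## Derived inference

exp(beta1) is the PM rate ratio per 5 ug/m3 without smoke,
exp(beta1 + beta2) with smoke (variance by w'Sigma w), and exp(beta2)
the modification factor, also reported as (exp(beta2) - 1) x 100
percent.  For the two-fraction model the percent increase attributable
to smoke at concentrations (PM2.5, PM10-2.5) is
(exp(beta2 PM2.5/5 + beta4 PM10-2.5/5 + beta5) - 1) x 100 with variance

PM2.5^2 Var(b2) + PM10-2.5^2 Var(b4) + Var(b5)
  + 2 PM2.5 PM10-2.5 Cov(b2, b4) + 2 PM2.5 Cov(b2, b5)
  + 2 PM10-2.5 Cov(b4, b5)

(concentrations on the per-5-ug/m3 scale).  Surface estimates are masked
to cells within 5 ug/m3 (Euclidean, raw concentration plane) of an
observed retained wildfire point, to prevent extrapolation; significance
is two-sided Wald p < 0.05 with no multiplicity correction.  Confidence
intervals are Wald throughout, exponentiated from the log scale.

## The synthetic world

The generator produces data with the statistical structure the analysis
assumes, with known truth, so that recovery can be tested.  Defaults
describe a six-year (2192-day) study:

* **Smoke calendar**: Poisson episodes (4/year) with lognormal lengths
  (median 5 days), starts weighted toward mid-August; about 85% of smoke
  days are affected for 24 h and ~97% for more than 20 h (short
  qualifier gaps emulate monitor maintenance).  Expected totals are
  around 170-200 smoke days per six years, with the counts of days
  preceded by 2+ and 6+ smoke days decreasing in the observed pattern.
* **Monitors**: four monitors with staggered activity windows (monitor 1
  continuously active -- mirroring a study area where only one monitor
  covered the whole period), patient-count weights, 1%/day per-fraction
  dropout elsewhere.  Fine PM is lognormal with a winter-peaking
  seasonal baseline and AR(1) day-to-day persistence (multi-day
  stagnation episodes, so non-wildfire rolling-average maxima are
  realistically heavy); smoke days add a shared lognormal spike to PM2.5
  scaled by affected hours, and only a small additive bump (0.7 ug/m3)
  to the coarse fraction; PM10 = PM2.5 + PM10-2.5 by construction.
  Resulting non-wildfire/wildfire PM2.5 means are about 7.5/19 ug/m3
  with coarse means nearly unchanged -- the asymmetry that motivates the
  two-fraction model.
* **Weather**: seasonal temperature (annual mean ~13 C, warm-season
  ~24 C) with AR(1) noise; RH anticorrelated with temperature
  (correlation ~ -0.8).
* **Visits**: NB counts from the same linear predictor the fitter
  assumes.  The day-of-year seasonality of visits enters through the
  temperature coefficient (-0.012 per degree C of T7: colder weeks see
  more visits); the spline's target f(t) is a slow multi-year cycle
  (amplitude 0.10, period 3 years).  Putting the annual cycle into
  temperature rather than f(t) keeps the default 10-knot spline
  well-specified; a 10-knot spline cannot track six annual oscillations,
  and a generator that demanded it would test basis capacity, not the
  method.  Dispersion theta = 12 gives variance/mean ~ 1.7 at the
  long-run mean of ~8.6 visits/day (the fitted dispersion is not
  published for the motivating study; this value merely makes
  overdispersion visible at a plausible clinical scale).  AR feedback
  uses the previously generated counts; pre-study lags are fixed at 8.

What the generator does **not** emulate: spatial smoke transport (the
calendar is marked, not a plume model), measurement error correlated
across fractions, reporting artifacts in visit counts (holiday closures
changing *capture* rather than incidence), and long-term secular trends
in healthcare utilisation.  A green recovery test therefore establishes
that the estimator is consistent and correctly calibrated *under the
stated world*, not that any particular epidemiological estimate is
right.

## Verification strategy

* Exposure rules are checked exactly against a day-by-day brute-force
  recomputation on small panels, plus hand-computed cases (weighted
  averages, tri-state truth table, strict exceedance boundary).
* The penalized IRLS is checked against three independent oracles:
  `stats::glm` in the Poisson limit (theta = 1e10, lambda = 0), a
  textbook IRLS written separately in the test helpers, and direct BFGS
  maximization of the penalized NB log-likelihood on small designs
  (agreement <= 1e-6); the full GAM is cross-checked against `mgcv`.
* Parameter recovery: over replicated six-year worlds with true
  beta2 = 0.06 per 5 ug/m3, the mean estimate is within 0.01 of truth
  and 95% Wald intervals cover within [90%, 98%]; under the null the
  false-positive rate at p < 0.05 is consistent with 5% (exact binomial
  check).  Replicate counts (100 effect / 60 null) are reduced from the
  nominal 200 to fit a single-CPU time budget; the seed (20130101) was
  fixed in advance.
* The pipeline is bit-reproducible: identical config and seed give
  byte-identical reports.

## Known limitations

* The inner optimization is dense; designs beyond a few hundred columns
  would need sparse or blockwise linear algebra.
* Smoothness selection uses the working-model REML approximation, not
  exact Laplace REML; for very low counts the two can differ.
* Sensitivity variants re-report the single-fraction modification
  factors; two-fraction sensitivity surfaces can be produced by
  refitting with a modified `model_spec` but are not part of the
  standard report.
* `NA` handling in lag averages is strict by design; series with heavy
  missingness lose many observations rather than changing the estimand
  silently.
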