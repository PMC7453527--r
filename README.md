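# smokegam

Does particulate matter harm asthma patients more when the particles come
from wildfire smoke?  `smokegam` implements a complete time-series
effect-modification analysis for answering that question from daily data:
counts of asthma emergency-department/urgent-care visits, per-monitor
PM2.5 / PM10–2.5 / PM10 concentrations, hourly smoke-qualifier flags, and
daily weather.  It is aimed at air-pollution epidemiologists who want the
full pipeline — exposure construction, penalized negative-binomial GAM,
derived inference — as tested, reusable code, with a synthetic-data
generator so every stage can be exercised without access to protected
health records.

## The model

Daily visit counts *y<sub>t</sub>* are modelled as overdispersed
(negative-binomial) counts with log mean

log *E*(*y<sub>t</sub>*) = α + γ·DOW + δ·holidays + *f*(*t*) +
ζ·temp₇ + η·AR + β₁·PM + β₂·(PM × WF) + β₃·WF + θ·MON

where *f*(*t*) is a penalized cubic regression spline of time whose
smoothness is selected automatically (REML-type criterion, GCV fallback),
temp₇ is a rolling 7-day mean temperature, AR are autoregressive terms
log(1 + *y*<sub>t−j</sub>) for lags 1–10, PM is the patient-count-weighted
concentration (per 5 μg/m³) for one fraction and lag set (lag 0, lags 0–2
or lags 0–6), WF is the matching tri-state wildfire indicator, and MON are
monitor-activity indicators.  Key exposure rules:

* a day is a **wildfire day** if any hour was flagged as smoke-affected;
* the multi-lag wildfire indicator is 1 only if *all* lags are wildfire
  days, 0 only if *none* are, and the observation is **excluded** for
  mixtures;
* wildfire observations whose lag-averaged PM2.5 strictly exceeds the
  maximum over non-wildfire observations are **excluded** (separately per
  lag set), so wildfire and non-wildfire PM are compared over overlapping
  concentration ranges.

exp(β₂) is the **wildfire modification factor** — the multiplicative
change in the PM rate ratio when smoke is present — reported also as
(exp(β₂) − 1) × 100 percent.  A two-fraction variant (lag-0 PM2.5 and
PM10–2.5 with separate interactions) yields the percent increase in
visits attributable to smoke at any (PM2.5, PM10–2.5) level, with
delta-method variances w′Σw for every derived quantity.

## Worked example

```r
library(smokegam)
sim   <- simulate_study(n_days = 2192, seed = 1)   # six synthetic years
study <- build_study_panel(sim$exposure, sim$weather, sim$visits)
fit   <- fit_nb_gam(assemble_design(study, model_spec("single", "pm25", "0")))
print(fit)
#> Negative-binomial GAM fit
#>   model: single fraction=pm25 lags=0
#>   n = 2174, deviance = 2234.74, dispersion = 13.063
#>   smoothing parameter = 8.275, spline edf = 5.86 (reml)

m <- wildfire_modification(fit)
print(m$non_wildfire)   # PM2.5 rate ratio per 5 ug/m3 without smoke
#> rate ratio 1.0013 (95% CI 0.9780-1.0251), +0.13%, p = 0.917
print(m$wildfire)       # ... with smoke
#> rate ratio 1.0842 (95% CI 1.0155-1.1576), +8.42%, p = 0.0156
print(m$modification)   # multiplicative change due to smoke
#> rate ratio 1.0828 (95% CI 1.0098-1.1611), +8.28%, p = 0.0254
```

The generating truth behind this simulation has β₂ = 0.06 per 5 μg/m³
(a 6.2% modification); the fitted 8.3% (CI 1.0–16.1%) is one draw from
its sampling distribution.  The closed-form two-fraction surface at
PM2.5 = 20 and PM10–2.5 = 15 μg/m³ with the published coefficients:

```r
two_fraction_percent(0.0747, 0.0341, -0.2259, pm25 = 20, pm_coarse = 15)
#> 19.14845
```

i.e. smoke at those concentrations is associated with a 19.1% increase in
visits.

## Command line

```sh
Rscript inst/cli/smokegam run-all --config config.json --seed 1 --outdir out/
```

Subcommands `simulate`, `build-exposure`, `fit`, `infer`, `sensitivity`,
`run-all` run successive prefixes of the pipeline; outputs include
`exposure.csv`, `fits.json`, `model_grid.csv`, `surface.csv`,
`sensitivity.csv` and a deterministic `summary.json`.  A config names
either real input CSVs (`paths`) or a `synthetic` block; see
`?read_run_config`.

## Further reading

The methods vignette (`vignettes/methods.Rmd`) documents the model and
its assumptions, the smoothness/dispersion selection, every exposure
rule, what the synthetic world does and does not emulate, and the design
decisions taken where conventions differ.
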