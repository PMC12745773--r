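# heatmort

Distributed-lag heat-mortality models with temporal compounding and
counterfactual attribution, for department-day panels of daily deaths
and weather.

## The problem

Heat waves raise daily mortality, and the effect of a hot day depends
on the days before it: sequences of hot days can be far deadlier than
the same days in isolation. Standard exposure-response functions (ERFs)
treat lagged temperatures as additively separable and can misstate the
toll of compound events. heatmort estimates both the standard and the
compounding ERF on regional daily panels, propagates coefficient
uncertainty, predicts event mortality against climatological baselines,
attributes deaths to counterfactual temperature differences, and
contrasts pre- versus post-adaptation response functions — with a
synthetic-data generator whose ground truth is known exactly, so the
whole chain is testable end to end.

## The models

Excess mortality baseline (two-way fixed effects for log mortality
rate `M`, department `i`, day-of-year `d`, year `y`):

    log(M_idy) = mu_iy + delta_id + eps_idy

Standard ERF: a 4th-order polynomial `f` in daily mean temperature at
lags 0..L (default L = 5), interacted with department mean climate
`Tbar_i`, plus lagged humidity/precipitation controls `X` and the same
fixed effects:

    log(M_idy) = sum_j [ f(T_i(d-j)y) + f(T_i(d-j)y) x Tbar_i ]
               + sum_j lambda_j X_i(d-j)y + mu_iy + delta_id + eps_idy

Temporal compounding adds, for each lag j, the interaction of that
day's polynomial with a transform `g` of the preceding day's
temperature (level, anomaly, or a one-knot natural cubic spline):

    ... + f(T_i(d-j)y) x g(T_i(d-j-1)y) + ...

Estimation absorbs both fixed-effect dimensions by alternating
demeaning (compiled), covariance is the CR1 department-clustered
sandwich, and uncertainty propagates through 500 multivariate-normal
coefficient draws; intervals are 2.5th-97.5th percentiles.

## Worked example

```r
library(heatmort)

# simulate a 6-department, 1990-2003 panel with a known heat-mortality
# response and an August 2003 heat wave
cfg <- generator_config(n_departments = 6, years = 1990:2003, seed = 42)
event <- event_spec(2003, start_cday = 214, end_cday = 227,
                    peak_uplift = 8, profile = "triangular")
inj <- inject_event(generate_panel(cfg), event)
panel <- with_department_climate(inj$panel, period = c(1990, 2002))

# fit the compounding exposure-response model on pre-event data
spec <- model_spec(compounding = "previous_level")
fit <- fit_erf(build_design(panel, spec, period = c(1990, 2002)),
               period = c(1990, 2002))
samples <- sample_coefficients(fit, n = 500, seed = 1)
fit
#> heat_fit: 84 coefficients; 28452 obs; 6 clusters; 2268 absorbed
#> fixed-effect df ; period 1990-2002

# how much deadlier is a 30 C day after another 30 C day?
tbar <- population_weighted_tbar(panel)
me_seq <- marginal_effect(samples, c(30, 30), c(20, 20), tbar = tbar)
me_iso <- marginal_effect(samples, c(30, 20), c(20, 20), tbar = tbar)
#> 30C after 30C: +35.1% [11.6, 63.2]
#> 30C after 20C: +28.6% [16.7, 42.2]

# predict the event against climatology and attribute deaths to a
# -1.2 C counterfactual cooling
clim <- build_climatology(panel, c(1990, 2002))
win <- sort(unique(inj$event_days$date))
scen <- scenario_from_panel(panel, win, spec)
pred <- predict_event_deaths(samples, scen, clim)
mean(prediction_totals(pred))
#> event heat-related deaths: 501
cool <- apply_deltas(scen, -1.2, label = "GMT+0.0")
attributable_deaths(pred, predict_event_deaths(samples, cool, clim))
#> attributable deaths (observed - GMT+0.0): 176.6 [144.8, 216.7],
#> 35.2% of event total; ensemble 500
```

The marginal effects are percent changes in mortality relative to two
consecutive days at 20 C, evaluated at the population-weighted mean
department climate; the attribution pairs each coefficient draw's
observed-scenario prediction with the same draw's counterfactual
prediction, so the interval reflects coefficient uncertainty in the
difference itself. The generator's true values for this configuration
(+43% for consecutive 30 C days, +22% in isolation) sit inside the
fitted intervals.

A full pipeline — standard and compounding fits on the pre-event
period, out-of-sample event prediction, excess mortality, attribution,
post-period refits and warmed-scenario projections — is available as
`run_full(default_pipeline_config())`, configurable from YAML
(`read_pipeline_config()`), with a thin command-line wrapper in
`inst/scripts/heatmort.R`.

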