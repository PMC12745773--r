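---
title: "Models and methods: distributed-lag heat-mortality estimation with temporal compounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
```

# The scientific problem

Severe heat waves kill, and two questions dominate their epidemiology:
how much of an event's death toll is attributable to anthropogenic
warming, and how much can adaptation reduce the toll of the next,
hotter event. Both questions run through an exposure-response function
(ERF): a fitted relationship between daily temperature and the log
mortality rate of an administrative region. heatmort implements the
full chain — ERF estimation on department-day panels, uncertainty
propagation, climatological event prediction, counterfactual
attribution, and adaptation contrasts — together with a synthetic-data
generator whose ground truth is known exactly, so that every stage can
be validated end to end.

# Models

## Excess mortality baseline

For department $i$, day-of-year $d$, year $y$, the baseline model for
the log mortality rate $M_{idy}$ (deaths per 100,000 per day) is

$$\log(M_{idy}) = \mu_{iy} + \delta_{id} + \epsilon_{idy},$$

a two-way additive decomposition giving each department its own
seasonal cycle ($\delta_{id}$) and long-term trend ($\mu_{iy}$).
`fit_baseline()` solves it by alternating within-group means, which is
the exact least-squares solution; the level ambiguity between the two
terms is fixed by constraining each department's seasonal terms to mean
zero (predictions are invariant to this choice). Excess deaths over a
window are observed deaths minus the exponentiated baseline prediction
converted to counts; no smearing correction is applied to the
exponentiated prediction, and the option is deliberately left out
rather than half-implemented (`excess_deaths()` documents this).

## Standard exposure-response function

The standard ERF regresses log mortality rates on a fourth-order
polynomial in daily mean temperature at lags $0..L$ (default $L = 5$),
each lag's polynomial optionally interacted with the department's
long-term mean temperature $\bar T_i$ (spatial heterogeneity), plus
lagged relative-humidity and precipitation controls, with
department-by-year and department-by-day-of-year fixed effects:

$$\log(M_{idy}) = \sum_{j=0}^{L} f(T_{i(d-j)y}) +
  f(T_{i(d-j)y})\times \bar T_i +
  \sum_{j=0}^{L} \lambda_j X_{i(d-j)y} + \mu_{iy} + \delta_{id} +
  \epsilon_{idy}.$$

Coefficients are estimated independently per lag (no smooth constraint
across the lag dimension). Temperatures enter uncentered; every
downstream quantity is a contrast, which differences out the level.

## Temporal compounding

The compounding model additionally interacts each lag's polynomial with
a transform $g(\cdot)$ of the temperature on the day preceding that
lag — lag $j$ is interacted with the day at lag $j+1$:

$$\ldots + f(T_{i(d-j)y}) \times g(T_{i(d-j-1)y}) + \ldots$$

`model_spec(compounding = ...)` offers three $g$: the previous day's
level (default), its anomaly from climatology (less collinear with the
current day), and a natural cubic spline with one interior knot
(default 11.7 deg C, a typical mid-latitude sample median; boundary
knots at the estimation-sample range so the basis is reproducible at
prediction time). All $P$ powers are interacted with $g$; the printed
form of the interaction does not resolve per-power detail, and
interacting all powers is the interpretation that nests the
no-interaction model.

## Estimation and inference

Both fixed-effect dimensions are absorbed by alternating within-group
demeaning (compiled code; tolerance $10^{-10}$ on the maximum
adjustment relative to column scale, capped at 10,000 sweeps — balanced
panels converge in a handful). Slopes on the demeaned design equal
explicit dummy-variable least squares, which the test suite asserts to
$10^{-8}$. Columns demeaned to numerically zero variance are
fixed-effect-collinear and are dropped with a warning.

Covariance is the CR1 cluster-robust sandwich with clusters at the
department level, scale factor $\tfrac{G}{G-1}\tfrac{N-1}{N-K}$, where
$K$ counts the substantive regressors plus absorbed degrees of freedom
($G_1 + G_2$ minus the number of connected components of the group
graph). The small-sample correction is not stated in the literature
this design follows; CR1 (the Stata default) is assumed and verified
against an independent sandwich implementation in the tests.

Uncertainty propagates by sampling coefficient vectors (default
$n = 500$) from $\mathcal{N}(\hat\beta, \hat V)$ via the symmetric
eigen factorization, clipping negative eigenvalues at zero. All
intervals are 2.5th-97.5th percentiles across draws.

## Response curves, surfaces, support

`marginal_effect()` contrasts the lag-0 regression terms at a
(current, previous) scenario against a reference pair (default two
consecutive days at 20 deg C) per draw, and maps log differences to
percent changes with the exact transform $100(e^\Delta - 1)$ (the
linear approximation is available behind a flag). `cumulative_effect()`
sums all lags for a focal day given its realized history.
`compounding_surface()` evaluates the two-dimensional
(previous, current) surface; cells whose 1 deg C x 1 deg C bin contains
no consecutive-day pair in the estimation sample (`support_mask()`)
carry no value, and response curves flag extrapolation outside the
current-day range observed conditional on the previous-day bin.

## Event prediction and attribution

`predict_event_deaths()` compares, per draw and department-day, the
fitted cumulative response along the scenario temperature path against
the climatological path for the same calendar days, and multiplies the
resulting percent change by the climatological mean death count for
that department and calendar day. Negative contributions (days cooler
than climatology) are retained. Counterfactual scenarios are built by
`apply_deltas()`: a region-wide daily temperature delta applied
uniformly to every department (the delta-method bias correction used
with learned counterfactual temperature predictions). History days
before the delta table reuse the first delta so no artificial jump
enters the lag structure; this is configurable. Attribution
(`attributable_deaths()`) differences paired draws — never summaries —
and pools draw x delta-source ensembles; the attributable fraction is
computed per draw. `project_event()` applies period-tagged coefficient
samples to warmed scenarios, enabling the pre/post-adaptation contrast.

# The synthetic data generator

`generate_panel()` simulates department-day panels with the structure
the estimators assume: a seasonal temperature cycle (amplitude 8 deg C,
peaking around 20 July) plus AR(1) anomalies (rho = 0.7, innovation sd
2.5 deg C), department mean climates evenly spaced over 8-18 deg C,
population 650,000 per department, and Poisson death counts with
baseline rate 2.7 per 100,000 per day (about 17 deaths per department
per day) — magnitudes chosen to resemble mid-size French departments.
Seasonal and anomaly series are centered so each department's realized
long-term mean temperature equals its configured value exactly, which
makes the climate-recovery checks sharp. A weather burn-in before the
first panel day supplies lag histories.

The true response is parameterized on centered scaled coordinates
($u = (T-20)/10$, previous-day $v$, climate $w = (\bar T_i - 13)/5$)
and lies exactly in the span of the regression design, so fitted
contrasts are comparable with the truth. The default truth is U-shaped
with a flat thermal-comfort zone (below +5% between roughly 12 and
25 deg C), a lag-0 effect of +22% for a 30 deg C day after a 20 deg C
day rising to +43% after another 30 deg C day — preserving the roughly
1.8x compounding ratio reported for pre-2003 France — heat effects
concentrated in lags 0-2, and a negative climate interaction (warmer
departments respond less). The compounding shape satisfies $Q(u) = 0$
at $T = 0$ deg C so that, expanded into raw powers, the truth has no
pure previous-day term: the raw-basis lag-0 estimand then coincides
with the naive lag-0 slice of the truth. `true_log_response()` is the
single oracle from which every downstream "truth" (parameter recovery,
event excess, attribution) derives. In `expected_value` mode the
deaths column stores exact expectations (hence non-integral values),
making the generator an exact oracle; Poisson mode is the default and
leaves the log-rate least-squares estimator deliberately misspecified
in the way count data always do, which the coverage-based tests must
tolerate.

An optional adaptation break (`adaptation = list(year, factor)`)
scales all response coefficients from a given year onward, emulating
post-event moderation of the heat-mortality relationship; the pipeline
default halves the response from 2004.

`inject_event()` raises window temperatures per an event profile
(constant or triangular ramp, default peak +8 deg C, echoing the
magnitude of the August 2003 anomaly) and re-simulates mortality from
the truth on exactly the days whose lag history touches the window, so
the event's true excess deaths are computable in closed form.

## What the generator does not emulate

Weather is spatially independent across departments; real temperature
fields are strongly correlated, which mainly affects how much the
department-clustered standard errors are exercised. Anomalies are
Gaussian AR(1): there are no blocking-type regimes whose multi-week
persistence exceeds what the day-to-day autocorrelation implies, no
humidity-temperature dependence, and no mortality displacement
(harvesting). Passing tests therefore demonstrate the correctness of
the estimators and accounting on data satisfying the model's
assumptions, not robustness to the full structure of observed weather
and mortality.

A consequence worth stating plainly, because it shapes one deliberate
test outcome: in an AR(1) world, consecutive hot days are common in
the estimation sample, so the additively-separable model absorbs most
of the compounding interaction through the conditional expectation of
the previous day given the current one, and predicts a compound event
almost as well as the interaction model does. Separately, the
climatology-referenced prediction estimand systematically exceeds the
event-minus-no-event excess: the event's deadliest days are exactly
the days riding positive anomalies, where the climatological reference
understates no-event mortality, and the event partially absorbs into
the seasonal baseline. At desk-scale panels these two effects are
larger than the standard model's compounding shortfall, so the
documented headline behaviour of real-world compound events — the
standard model underpredicting while the interaction model covers the
excess — does not reproduce under the generator's assumptions. The
acceptance suite encodes that directional experiment faithfully and
reports its failure rather than weakening it; the attribution
experiments, which difference paired scenarios and cancel the
reference-path effect, recover their closed-form truths.

# Numerical choices

- Zero-death department-days are excluded from estimation with a
  reported count (an optional +0.5 continuity correction exists, off by
  default); at the default simulated rates zeros are vanishingly rare.
- Lags never cross gaps in a department's daily series or the series
  start; rows lacking history are dropped and counted, never padded.
- Missing weather values are an error, not imputed.
- Dates are matched across years by calendar day (29 Feb exists only in
  leap years and its climatology averages leap years only).
- The normal-equations solve scales columns to unit RMS before the
  Cholesky factorization (raw quartic temperature columns span ~6
  orders of magnitude); rank deficiency falls back to a pivoted QR to
  name the offending columns.
- Support bins are half-open 1 deg C cells; the reference pair for
  surfaces must lie inside the evaluation grid.
- All randomness flows from one master seed through named substreams
  (generation, sampling, injection), so stages are independently
  reproducible.

# Study sizes used by the tests

Unit tests run on toy panels (2-5 departments, 2-14 years). The
acceptance experiments use: 200 Monte Carlo replicates of 10
departments x 25 years for interval coverage of the compounding
contrast; 50 replicates of 8 departments x 16 years for the
directional event experiment; 8 departments x 14 years for attribution
recovery; and the pipeline demonstration runs 10 departments x 33
years. These sizes give sampling error comfortably inside the
acceptance tolerances while keeping a full run of the suite on one
core in the tens of minutes.

# Known limitations

- OLS on log rates, not a count model: estimates inherit the small
  Jensen bias of log-Poisson outcomes; coverage-based criteria absorb
  it at the default rates (~17 deaths/day), but very small populations
  would need a GLM, which is out of scope.
- Ten clusters is few for CR1; the percentile intervals are honest
  about this only through the coverage experiment, not theory.
- Quartic polynomials extrapolate badly outside support; surfaces and
  curves flag extrapolation, but event predictions at unprecedented
  temperatures still rely on the polynomial tail, exactly as in the
  literature this design follows.
- The counterfactual machinery consumes daily delta tables as data;
  generating physically-based deltas (e.g. from a trained emulator) is
  out of scope, and the bundled delta generator is labelled synthetic.
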