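---
title: "Methods: heat stress and heat-attributable mortality projection"
author: "heatmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat stress and heat-attributable mortality projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatmort)
```

# Scope

`heatmort` implements a complete pipeline for projecting heat stress and
heat-attributable mortality over gridded scenario climate: a piecewise heat
stress index (HSI) from daily temperature and relative humidity; site-level
distributed lag nonlinear models (DLNM) of daily death counts; multivariate
random-effects meta-analysis pooling site curves into regional
exposure–response curves; projection of attributable deaths over gridded
climate and population; Monte Carlo and multi-model ensemble uncertainty;
and a random-forest decomposition of temperature versus humidity
contributions. A synthetic-data module generates inputs with the
statistical structure the analysis assumes, so the whole pipeline is
testable without any external data.

# The heat stress index

The HSI is the US-NWS-style heat index expressed in degrees Celsius. It is
piecewise:

* below 80 °F it is Steadman's simple formula, which with `t` in °C and
  output on the Fahrenheit scale reads `1.98 t + 24.9 + 0.047 RH`
  (algebraically `1.1 T_F − 10.3 + 0.047 RH` at `T_F = 1.8 t + 32`);
* at or above 80 °F it is the nine-term Rothfusz regression with its
  Fahrenheit-scale coefficients (`2.04901523 T_F − 42.379 + …`),
* minus a low-humidity adjustment `((13 − RH)/4) · sqrt(1 − |9t − 315|/85)`
  when RH < 13 % and 26.7 °C ≤ t ≤ 44.5 °C,
* plus a high-humidity adjustment `((RH − 85)/10) · (275 − 9t)/25` when
  RH > 85 % and 26.7 °C ≤ t ≤ 30.5 °C.

**Unit resolution.** The Rothfusz coefficients only make sense on the
Fahrenheit scale, and the adjustment windows 26.7/30.5/44.5 °C are exactly
80/87/112 °F; the Celsius-substituted forms above are algebraically
identical to the NWS originals. The default `mode = "nws"` therefore
computes internally in °F and converts the result to °C. Some published
transcriptions state all quantities in °C; `mode = "celsius"` evaluates
that reading verbatim (no unit conversion, with the simple-formula branch
taken whenever the Rothfusz value falls below 26.7) so the two conventions
can be compared. The Celsius-literal output is not a physically meaningful
temperature and is provided for auditability only. The square root in the
dry adjustment is applied even where transcriptions omit the radical, since
the term is otherwise negative for most of its window.

The `nws` mode is verified in the test suite against an independently coded
Fahrenheit-native reference on a 200 × 100 (t, RH) grid to below 1e−9 °C.
Missing inputs propagate (`NA` in, `NA` out); humidity outside [0, 100] and
non-physical temperatures are rejected.

# Site-level exposure–response: the DLNM

Daily deaths at a surveillance site are modelled by a quasi-Poisson GLM
with log link:

```
log E(mort_i) = alpha + cb(HSI, lag)_i' beta + ns(time_i, 7 df/year) + DOW_i
```

The cross-basis `cb` is the tensor product of a natural cubic spline over
the exposure axis and a natural cubic spline (with intercept) over lags
0–21 days. Twenty-one days of lag capture the delayed effect of heat,
including short-term displacement. Defaults, configurable through
`crossbasis_spec()`:

* exposure basis: df 4, internal knots at the 10th/75th/90th percentiles of
  the observed HSI, boundary knots at the observed range — standard
  practice in temperature–mortality DLNM work;
* lag basis: df 4 with intercept, internal knots equally spaced on the
  log-lag scale (at lags 21^(1/3) ≈ 2.8 and 21^(2/3) ≈ 7.6), reflecting
  the concentration of structure at short lags;
* seasonality and trend: natural cubic spline of time with 7 df per year;
* day of week: six indicator contrasts against Monday.

Rows whose 21-day lag history is incomplete are dropped from the
likelihood, not imputed. Dispersion is estimated by Pearson χ²/df and
scales the coefficient covariance. When several sites are to be pooled the
exposure knots must be fixed once (e.g. from the pooled HSI distribution)
so all sites share one basis; `fit_site_model()` otherwise resolves knots
per site.

`reduce_overall()` sums the lag-basis contributions over lags 0–21 into one
coefficient per exposure-basis function — a linear map, so the covariance
propagates exactly as `B V B'` — yielding the overall cumulative
exposure–response curve. `find_mmhsi()` locates the minimum-mortality HSI
(MMHSI) as the argmin of the cumulative log relative risk on a 0.1 °C grid
within a search window defaulting to the 1st–99th percentile of the
observed HSI (boundary artifacts are thereby excluded); ties resolve to the
lowest HSI and a flat curve (log-RR range < 1e−10) returns the window
midpoint with a warning. The curve is centred so `RR(MMHSI) = 1` exactly;
`rr_at()` returns relative risks with delta-method 95 % intervals.
Beyond the observed HSI range the natural spline extrapolates log-linearly,
which is the intended behaviour on future climates warmer than the
calibration period; outside-range evaluation warns unless
`extrapolate = TRUE`.

# Regional pooling

Site-reduced coefficient vectors `y_s` with covariances `V_s` are pooled
per subregion under the multivariate random-effects model
`y_s ~ N(mu, V_s + psi)`. The constrained-likelihood convention for this
model is restricted maximum likelihood: `pool()` maximises the REML
objective with `psi` parameterised through its Cholesky factor (log
diagonal), which enforces positive semi-definiteness; optimisation uses
Nelder–Mead with one restart (Brent in the univariate case), falling back
to a method-of-moments estimate if the optimiser fails. The univariate
case is cross-checked in the tests against an independent REML
implementation (`metafor::rma`) to four decimals.

`blup()` gives each site the standard shrinkage predictor
`mu + psi (psi + V_s)^{-1} (y_s − mu)`; a singular `psi + V_s` is
ridge-stabilised with a warning. The regional curve used for attribution
is the pooled mean `mu` with covariance `(sum_s (V_s + psi)^{-1})^{-1}`,
re-centred at its own MMHSI — BLUP is exposed for site-level prediction,
but the region is represented by `mu` directly, the simplest defensible
mapping from site predictions to one curve per region.

Heterogeneity is summarised by Cochran's Q at the fixed-effect solution,
`df = (n_sites − 1) × dim`, its χ² p-value, and
`I² = max(0, (Q − df)/Q) × 100`.

# Attribution

For each grid cell and day with `HSI > MMHSI`, the attributable fraction is
`AF = (RR − 1)/RR` and the daily attributable deaths are
`D = Mt × Pop × AF`; days at or below the MMHSI contribute zero. Annual
cell totals `HD`, cell rates `HM = HD/Pop` (reported per mille), regional
sums `Reg_HD` and population-weighted regional rates
`Reg_HM = Reg_HD / sum(Pop)` follow by aggregation; regional sums are exact
sums, so national totals equal the sum over subregions by construction.
The AF floor at zero is defensive only — above the minimum of a U-shaped
curve RR exceeds 1.

Conventions: the baseline period is 1995–2014; future decades are
half-open windows (2030s = [2030, 2040)); change ratios are
`future_mean / baseline_mean × 100 %`. The baseline death rate `Mt` is held
at its baseline value for future years (the projection assumes comparable
baseline mortality and a stable exposure–response relationship), but is a
per-year input so sensitivity runs can vary it. Decadal population
snapshots are interpolated linearly in time; fine-to-coarse regridding
(0.125° → 0.25°) interpolates density bilinearly at coarse cell centres
and rescales so the national total is conserved (machine precision in
practice, < 0.1 % required). Leap days are included with no annualisation
correction. A cell-year missing more than 10 % of days is excluded with an
error.

A documented example configuration of regional MMHSI values for the seven
Chinese climatic subregions (NE/NC/NW/EC/CC/SW/SC = 24/26/25/25/35/29/32
°C) ships as `mmhsi_regions_cn()`; it is a reference configuration, not a
quantity the package recomputes.

# Uncertainty

Two sources are propagated: exposure–response estimation uncertainty and
between-model climate spread. `sample_coefficients()` draws (by default
1000) coefficient vectors from the multivariate normal implied by the
curve's covariance; a non-PSD covariance is projected to the nearest PSD
matrix by eigenvalue clipping, with a warning. Draws keep the curve's
stored MMHSI — no re-centring per draw, so the draws quantify uncertainty
in the curve given its reference.

The ensemble convention: the central estimate is the arithmetic mean over
models of per-model means; the 95 % interval spans the 2.5th–97.5th
percentiles of the flattened draw × model distribution with linear
interpolation between closest order statistics (R quantile type 7 — stated
because percentile dialects differ). The loop nests model → draw, and each
model receives its own RNG substream derived from the master seed, so
results are independent of evaluation order.

# Driver decomposition

For each inhabited cell-year with at least one heat-risk day, the feature
table holds the mean temperature and mean relative humidity over days with
`HSI > MMHSI` (the mean is the default aggregation statistic; max or a
percentile can be configured) and the annual heat-related mortality rate as
target. Cells with zero population and cell-years with no heat days are
excluded: the decomposition describes what drives variation in mortality
*once heat risk is established*, not whether humidity alone creates risk.
A regression random forest (variance-reduction impurity, 500 trees,
unrestricted depth, both features available at each split, bootstrap on,
fixed seed) is fitted and the two Gini importances are scaled to sum to
100 %. Cell-years from all models are pooled into one forest per region ×
scenario by default. The hyperparameters are chosen for stability of a
two-feature problem; shares are deterministic given the seed.

# The synthetic-data generator

The generator reproduces the statistical structure the analysis assumes,
not the physics behind it.

* **Climate** (`gen_climate()`): per cell, temperature = latitude-dependent
  mean + sinusoidal annual cycle (peak mid-July) + linear scenario trend +
  iid Gaussian day-to-day noise; relative humidity = baseline + linear
  trend + noise, clipped to [0, 100]. No spatial correlation by default
  (an optional 3 × 3 smoothing flag exists). The calendar is real, so leap
  years, day-of-week structure, and per-year spline df are all
  well-defined. The four default scenarios (`default_scenarios()`) span
  warming rates of 0.18–0.93 °C/decade, chosen so cumulative 2015–2100
  warming matches the roughly 1.5–8 °C heat-stress range reported across
  the Tier-1 SSP scenarios, with small negative humidity trends keeping
  total RH change within a few percent.
* **Population** (`gen_population()`): a fixed seeded smooth random
  surface scaled to geometric national growth per decade.
* **Mortality** (`gen_site_mortality()`): counts with expected value
  `baseline × DOW × exp(sum_l w_l · logRR_true(HSI_{i−l}))` and variance
  `dispersion × mean` — negative binomial parameterised to match the
  quasi-Poisson assumption fitted downstream (Poisson when
  dispersion = 1).

**The true risk curve.** `true_risk_curve()` is a smooth U: log relative
risk rising with asymptotic slope `log_rr_slope` per °C above the minimum
and `cold_slope` below it, each arm a Huber-type hinge that is quadratic
within `smooth_halfwidth` (default 8 °C) of the minimum and exactly linear
beyond, distributed over lags 0–21 by weights summing to 1 (default:
geometric decay, ratio 0.7). Three properties of observed pooled
mortality curves motivate this shape, and each is also what makes
parameter recovery well-posed:

1. *Cold arm* (default slope equal to the heat arm): cold as well as heat
   elevates mortality, with cumulative 21-day cold effects of comparable
   magnitude to heat effects; without it the true curve is flat below the
   minimum, the minimum is not unique, and an argmin estimator cannot
   recover it.
2. *Smooth junction*: observed pooled curves are smooth near their
   minimum; a kinked V cannot be represented by a low-df spline basis, so
   recovery tests against a kinked truth measure basis approximation error
   rather than estimator quality.
3. *Between-site variation*: the two-stage random-effects model assumes
   site curves vary around the regional mean. The recovery study draws
   site minima from N(29, 0.75 °C) and site slopes lognormally (10 %)
   around 0.05/°C, and compares the pooled curve to the realised average
   of the site-level truths — the quantity the pooled mean estimates.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: spatially coherent weather; the anticorrelation
of temperature and humidity within seasons; demographic age structure and
adaptation; reporting artifacts in death counts; model-structural climate
biases beyond additive noise realisations. Parameter recovery on this
generator demonstrates the estimation machinery is correct under its own
assumptions, not that those assumptions hold in any particular dataset.

# Problem sizes and numerical choices

The recovery study uses 10 sites × 10 years at 10 expected deaths/day — a
county-scale surveillance site (≈ 0.5 M population at a crude death rate
near 7 ‰/year); site records in the null-calibration and Monte Carlo
studies span 7 years, matching the 2010–2016 span of the surveillance
records the data model emulates. The Monte Carlo coverage study uses 200
replicate pipelines with 100 draws and 3 pseudo-models; the demonstration
pipeline (`run_config()` defaults) uses a 5 × 5 cell grid, 3 sites, 2
scenarios, 2 pseudo-models and 100 draws. These sizes are the package's
documented study conditions and keep any single study in the minutes
range on one CPU.

Numerical details, for the record: the MMHSI grid step is 0.1 °C; REML
restarts once and falls back to method-of-moments; `psi + V_s` inversion is
ridge-stabilised at 1e−8 of the mean diagonal; covariance projection clips
negative eigenvalues at zero; all generators save and restore the caller's
RNG state; grid coordinates are cell-centred with longitudes in −180..180;
every output file of `run_pipeline()` carries the configuration hash and
the projection stage refuses curve files whose hash differs from the
active configuration.

# Known limitations

* Strong seasonal confounding adjustment (7 df/year) together with a
  smooth, heavily lagged exposure partially absorbs the cumulative heat
  effect; in simulations the recovered cumulative slope can attenuate by
  ~10 % relative to truth. This is a property of the design shared with
  the field's standard approach, not an implementation artifact.
* The argmin MMHSI estimator is biased toward the shallower arm of an
  asymmetric curve and toward the denser part of the exposure
  distribution; with a symmetric smooth truth and a climate placing the
  minimum centrally, recovery is within ±1 °C at the study sizes above.
* Projection onto future climate extrapolates the exposure basis
  log-linearly beyond the calibration range; this is an assumption, not an
  estimate.
* The cold arm of fitted curves is estimated but never attributed: only
  days above the MMHSI enter attribution. Cold-attributable mortality,
  harvesting decomposition, age/cause stratification, and economic
  valuation are out of scope.
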