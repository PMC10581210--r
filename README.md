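# heatmort

Projection of heat stress and heat-attributable mortality over gridded
scenario climate, for environmental epidemiologists and climate-health
impact modellers.

Rising temperatures and the humidity they interact with are projected to
increase heat-related deaths substantially over the coming decades, with
strong regional contrasts. Quantifying that burden requires chaining
several well-established pieces of methodology; `heatmort` implements the
whole chain as tested, reusable R functions, together with a synthetic-data
generator so that every stage — and the pipeline end to end — can be
exercised and validated without any external data.

## What it computes

**Heat stress index (HSI).** The NWS-style heat index in °C: Steadman's
simple formula below 80 °F, otherwise the Rothfusz regression

HI = −42.379 + 2.049 T_F + 10.143 RH − 0.2248 T_F·RH − 6.838×10⁻³ T_F²
− 5.482×10⁻² RH² + 1.229×10⁻³ T_F²·RH + 8.528×10⁻⁴ T_F·RH² − 1.99×10⁻⁶ T_F²·RH²

with low-humidity (RH < 13 %, 26.7–44.5 °C) and high-humidity (RH > 85 %,
26.7–30.5 °C) adjustments.

**Two-stage exposure–response.** Per site, a distributed lag nonlinear
model inside a quasi-Poisson regression,

log E(mort_i) = α + cb(HSI, lag 0–21)'β + ns(time, 7 df/yr) + DOW,

reduced to the overall cumulative curve RR(HSI) centred at the
minimum-mortality HSI (MMHSI); then multivariate random-effects
meta-analysis (REML) with BLUP shrinkage pooling the site curves into one
curve per subregion, with Cochran's Q and I² heterogeneity.

**Attribution.** For days with HSI above the MMHSI,
AF = (RR − 1)/RR, daily deaths D = Mt × Pop × AF, annual cell totals HD,
rates HM = HD/Pop (‰), regional aggregates, decadal means, and change
ratios against the 1995–2014 baseline.

**Uncertainty.** 1000-sample multivariate-normal draws of curve
coefficients crossed with multi-model climate ensembles; 95 % intervals
from the 2.5th–97.5th empirical percentiles.

**Drivers.** Random-forest Gini importance of heat-day temperature versus
humidity for annual heat-related mortality, scaled to 100 %.

## Worked example

```r
library(heatmort)

heat_index(c(26, 35.56, 38), c(50, 50, 10))
#> [1] 25.96111 42.03170 34.72703
```

26 °C at 50 % humidity is below the 80 °F threshold, so the simple formula
applies (26.0 °C feels like 26.0 °C); 35.56 °C at 50 % goes through the
Rothfusz regression (feels like 42.0 °C); 38 °C at 10 % humidity gets the
dry-air subtraction (34.7 °C).

The demonstration pipeline — synthetic climate for two scenarios and two
pseudo-models on a 5 × 5 grid, three simulated surveillance sites, DLNM
fits, pooling, projection, envelopes, drivers:

```r
cfg <- run_config(grid = grid_def(c(25, 25.75), c(110, 110.75), 0.25),
                  n_models = 2, n_sites = 3,
                  years_baseline = c(2000, 2004),
                  years_future = c(2030, 2039),
                  draws = 50, seed = 1, out_dir = tempfile())
res <- run_pipeline(cfg)

res$curves$R1$mmhsi
#> [1] 27.99526

res$decadal[, c("scenario", "window", "hm_permille", "lo", "hi", "ratio_pct")]
#>         scenario   window hm_permille        lo       hi ratio_pct
#> ssp126    ssp126 baseline    1.083975 0.8476277 1.310914  100.0000
#> ssp1261   ssp126    2030s    1.204196 0.9603277 1.430194  111.0907
#> ssp585    ssp585 baseline    1.126626 0.9090021 1.346867  100.0000
#> ssp5851   ssp585    2030s    1.811349 1.5851810 2.041132  160.7765
```

The fitted regional curve has its minimum-mortality HSI at 28.0 °C (the
generating truth is 29 °C). Heat-related mortality in this toy world rises
from about 1.08 ‰ at baseline to 1.20 ‰ in the 2030s under the low-emission
scenario (ratio 111 %) and to 1.81 ‰ (161 %) under the high-emission one;
`lo`/`hi` are the 95 % Monte-Carlo × ensemble envelopes. All output files
in `cfg$out_dir` carry the configuration hash, and re-running with the
same config and seed reproduces them byte for byte.

```r
res$drivers[, c("scenario", "temp_share", "hum_share")]
#>        scenario temp_share hum_share
#> ssp126   ssp126   83.45622  16.54378
#> ssp585   ssp585   84.80947  15.19053
```

In this synthetic world temperature dominates the variation of
heat-related mortality across cells (≈ 84 % of the Gini importance), as
expected since the generator couples risk to temperature much more
strongly than to humidity.

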