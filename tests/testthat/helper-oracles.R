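# Shared oracles and fixture builders. Everything is generated in code.

# Independent US-NWS heat-index reference, coded natively in Fahrenheit and
# structured differently from the package implementation (scalar, explicit
# branches). Input degC/%; output degC.
nws_reference <- function(t_c, rh) {
  tf <- t_c * 9 / 5 + 32
  hi_simple <- 1.1 * tf - 10.3 + 0.047 * rh
  if (hi_simple < 80) return((hi_simple - 32) * 5 / 9)
  hi <- -42.379 + 2.04901523 * tf + 10.14333127 * rh -
    0.22475541 * tf * rh - 6.83783e-3 * tf^2 - 5.481717e-2 * rh^2 +
    1.22874e-3 * tf^2 * rh + 8.5282e-4 * tf * rh^2 - 1.99e-6 * tf^2 * rh^2
  if (rh < 13 && tf >= 80 && tf <= 112.1) {
    hi <- hi - ((13 - rh) / 4) * sqrt((17 - abs(tf - 95)) / 17)
  } else if (rh > 85 && tf >= 80 && tf <= 86.9) {
    hi <- hi + ((rh - 85) / 10) * ((87 - tf) / 5)
  }
  (hi - 32) * 5 / 9
}

# Analytic exposure-response curve with log RR = slope * (x - mmhsi),
# linear exposure basis, fixed covariance scale for the slope.
linear_curve <- function(mmhsi = 0, slope = 1, var_slope = 0,
                         hsi_range = c(-10, 10)) {
  heatmort:::new_er_curve(
    list(exposure_knots = numeric(0), exposure_boundary = hsi_range,
         exposure_df = 1),
    coef = slope, vcov = matrix(var_slope), hsi_range = hsi_range,
    mmhsi = mmhsi, region_id = "toy")
}

# One-cell daily climate and its HSI, the common site fixture.
site_fixture <- function(years = c(2010, 2016), seed = 17, t_base = 24,
                         noise_sd = 2.5) {
  g <- grid_def(c(24, 24.25), c(110, 110.25), 0.25)
  sc <- scenario_spec("hist", warming_rate = 0.1, seasonal_amp = 8,
                      noise_sd = noise_sd, rh_mean = 65)
  cg <- gen_climate(g, sc, years, seed = seed, t_base = t_base)
  list(dates = cg$dates, hsi = heat_index_series(cg)[, 1, 1], cg = cg)
}

# A small population grid at 0.125 degrees for regridding tests.
fine_pop <- function(nlat = 8, nlon = 8, seed = 1) {
  pop <- heatmort:::with_seed(seed, matrix(stats::runif(nlat * nlon) * 100,
                                           nlat, nlon))
  structure(list(year = 2020,
                 lat = 20 + 0.125 * (seq_len(nlat) - 0.5),
                 lon = 110 + 0.125 * (seq_len(nlon) - 0.5),
                 res = 0.125, pop = pop),
            class = "population_grid")
}
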