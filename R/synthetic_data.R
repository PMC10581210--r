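# Synthetic gridded climate, decadal population, and site mortality with the
# statistical structure the downstream analysis assumes: sinusoidal annual
# cycle + linear scenario trend + iid Gaussian noise for climate, geometric
# growth for population, and overdispersed counts from a known lagged
# HSI-risk curve for mortality. All generators are pure functions of
# (parameters, seed).

# Evaluate `expr` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Define a regular latitude-longitude grid
#'
#' Cell-centred regular grid. Longitudes use the -180..180 convention.
#'
#' @param lat_range,lon_range Length-2 numeric extents (degrees).
#' @param res Cell size in degrees; must divide both extents.
#' @return A `grid_def` list with cell-centre coordinate vectors `lat`,
#'   `lon` and the resolution `res`.
#' @examples
#' g <- grid_def(c(20, 21), c(110, 111), res = 0.25)
#' length(g$lat)  # 4
#' @export
grid_def <- function(lat_range, lon_range, res) {
  stopifnot(length(lat_range) == 2, length(lon_range) == 2, res > 0)
  nlat <- (lat_range[2] - lat_range[1]) / res
  nlon <- (lon_range[2] - lon_range[1]) / res
  if (abs(nlat - round(nlat)) > 1e-8 || abs(nlon - round(nlon)) > 1e-8)
    stop("`res` must divide both extents", call. = FALSE)
  nlat <- round(nlat); nlon <- round(nlon)
  if (nlat < 1 || nlon < 1) stop("empty grid", call. = FALSE)
  structure(list(
    lat = lat_range[1] + res * (seq_len(nlat) - 0.5),
    lon = lon_range[1] + res * (seq_len(nlon) - 0.5),
    res = res
  ), class = "grid_def")
}

#' Daily climate series for one location
#'
#' @param dates Vector of `Date`s (contiguous daily calendar).
#' @param t Air temperature, degC.
#' @param rh Relative humidity, percent in `[0, 100]`.
#' @return A data frame of class `climate_series`.
#' @export
climate_series <- function(dates, t, rh) {
  stopifnot(length(dates) == length(t), length(t) == length(rh))
  check_t_rh(t, rh)
  structure(data.frame(date = as.Date(dates), t = t, rh = rh),
            class = c("climate_series", "data.frame"))
}

#' Emission/warming scenario for the climate generator
#'
#' Describes one scenario's trend structure: linear warming, a relative
#' humidity trend, the seasonal cycle, and day-to-day noise. Stands in for
#' the shared socioeconomic pathway (SSP) forcing scenarios of gridded
#' downscaled climate ensembles.
#'
#' @param name Scenario label, e.g. `"ssp585"`.
#' @param warming_rate Trend of daily mean temperature, degC per decade.
#' @param rh_trend Trend of relative humidity, percent per decade.
#' @param seasonal_amp Amplitude of the annual temperature cycle, degC.
#' @param noise_sd Day-to-day temperature noise SD, degC.
#' @param rh_mean Baseline relative humidity, percent (0-100 exclusive).
#' @return A `scenario_spec` list.
#' @seealso [default_scenarios()]
#' @export
scenario_spec <- function(name, warming_rate, rh_trend = 0,
                          seasonal_amp = 11, noise_sd = 3, rh_mean = 70) {
  stopifnot(is.finite(warming_rate), rh_mean > 0, rh_mean < 100,
            seasonal_amp >= 0, noise_sd >= 0, is.finite(rh_trend))
  structure(list(name = name, warming_rate = warming_rate,
                 rh_trend = rh_trend, seasonal_amp = seasonal_amp,
                 noise_sd = noise_sd, rh_mean = rh_mean),
            class = "scenario_spec")
}

#' Default scenario set
#'
#' Four scenarios spanning low to high emissions. Warming rates are chosen
#' so that the cumulative warming over a 2015-2100 projection roughly
#' matches the spread of heat-stress increases reported for the Tier-1 SSP
#' scenarios (about 1.5 degC under the lowest pathway to about 8 degC under
#' the highest); relative-humidity trends are small, keeping total RH change
#' within a few percent.
#'
#' @return Named list of [scenario_spec()] objects
#'   (`ssp126`, `ssp245`, `ssp370`, `ssp585`).
#' @export
default_scenarios <- function() {
  list(
    ssp126 = scenario_spec("ssp126", warming_rate = 0.18, rh_trend = -0.1),
    ssp245 = scenario_spec("ssp245", warming_rate = 0.35, rh_trend = -0.2),
    ssp370 = scenario_spec("ssp370", warming_rate = 0.60, rh_trend = -0.3),
    ssp585 = scenario_spec("ssp585", warming_rate = 0.93, rh_trend = -0.3)
  )
}

#' Ground-truth lagged risk curve for simulation
#'
#' Defines the true exposure-response used by [gen_site_mortality()]: a
#' smooth U-shaped log relative risk with its minimum at the
#' minimum-mortality HSI, rising with asymptotic slope `log_rr_slope` per
#' degC above it and `cold_slope` per degC below it, distributed over lags
#' 0-21 by nonnegative weights summing to 1. Each arm is a Huber-type
#' smooth hinge: quadratic within `smooth_halfwidth` degC of the minimum,
#' exactly linear beyond, with a continuous derivative that is zero at the
#' minimum. Observed pooled HSI-mortality curves are smooth U-shapes -
#' cold as well as heat elevates risk - and both the cold arm and the
#' smooth junction are what make the minimum identifiable and
#' representable by spline bases; set `cold_slope = 0` and
#' `smooth_halfwidth = 0` for a sharp pure-heat hinge. Used as the known
#' truth in parameter-recovery tests of the fitting pipeline.
#'
#' @param mmhsi_true Minimum-risk HSI, degC.
#' @param log_rr_slope Log relative risk per degC above `mmhsi_true`
#'   (cumulative over all lags); must be `>= 0`.
#' @param lag_weights 22 nonnegative weights over lags 0-21 summing to 1.
#'   Default: geometric decay with ratio 0.7.
#' @param cold_slope Log relative risk per degC below `mmhsi_true`
#'   (`>= 0`). The default 0.05 mirrors the heat arm: pooled
#'   temperature-mortality curves show cumulative cold effects of
#'   comparable magnitude to heat effects (relative risks around 1.5-2 at
#'   ten degrees below the minimum), and a symmetric V keeps the true
#'   minimum where smooth basis approximations place it.
#' @param smooth_halfwidth Half-width of the quadratic junction, degC
#'   (default 4); 0 gives a sharp kink.
#' @return A `true_risk_curve` list.
#' @export
true_risk_curve <- function(mmhsi_true = 29, log_rr_slope = 0.05,
                            lag_weights = NULL, cold_slope = 0.05,
                            smooth_halfwidth = 4) {
  if (is.null(lag_weights)) {
    lag_weights <- 0.7^(0:21)
    lag_weights <- lag_weights / sum(lag_weights)
  }
  stopifnot(length(lag_weights) == 22, all(lag_weights >= 0),
            abs(sum(lag_weights) - 1) <= 1e-12, log_rr_slope >= 0,
            cold_slope >= 0, smooth_halfwidth >= 0)
  structure(list(mmhsi_true = mmhsi_true, log_rr_slope = log_rr_slope,
                 lag_weights = lag_weights, cold_slope = cold_slope,
                 smooth_halfwidth = smooth_halfwidth),
            class = "true_risk_curve")
}

# Huber-type smooth hinge: 0 at 0, quadratic to half-width delta, then
# linear with unit slope; continuous first derivative.
smooth_hinge <- function(d, delta) {
  d <- pmax(0, d)
  if (delta <= 0) return(d)
  ifelse(d <= delta, d^2 / (2 * delta), d - delta / 2)
}

#' True cumulative log relative risk at given HSI values
#'
#' Evaluates the ground-truth V-shaped cumulative curve of a
#' [true_risk_curve()] (relative to its minimum), for comparing fitted
#' curves against truth.
#'
#' @param truth A `true_risk_curve`.
#' @param hsi Numeric HSI values, degC.
#' @return Cumulative log relative risk (0 at `mmhsi_true`).
#' @export
true_log_rr <- function(truth, hsi) {
  stopifnot(inherits(truth, "true_risk_curve"))
  delta <- truth$smooth_halfwidth %||% 0
  truth$log_rr_slope * smooth_hinge(hsi - truth$mmhsi_true, delta) +
    truth$cold_slope * smooth_hinge(truth$mmhsi_true - hsi, delta)
}

#' Generate gridded daily climate under a scenario
#'
#' Temperature per cell = latitude-dependent mean + sinusoidal annual cycle
#' (peak mid-July) + linear scenario trend + iid Gaussian noise. Relative
#' humidity = baseline + linear trend + noise, clipped to `[0, 100]`. No
#' spatial correlation unless `smooth = TRUE` (3x3 boxcar on each day's
#' fields).
#'
#' @param grid A [grid_def()].
#' @param scenario A [scenario_spec()].
#' @param years Inclusive integer year range, e.g. `c(1995, 2014)`.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param t_base Cell mean temperature at the southern grid edge, degC.
#' @param lat_gradient Cooling with latitude, degC per degree north.
#' @param rh_noise_sd Day-to-day RH noise SD, percent.
#' @param smooth Logical; apply a 3x3 spatial boxcar to each daily field.
#' @return A `climate_grid`: list with `dates`, `lat`, `lon`, and
#'   `day x lat x lon` arrays `t` (degC) and `rh` (percent).
#' @export
gen_climate <- function(grid, scenario, years, seed = 1L,
                        t_base = 24, lat_gradient = 0.5,
                        rh_noise_sd = 5, smooth = FALSE) {
  stopifnot(inherits(grid, "grid_def"), inherits(scenario, "scenario_spec"))
  if (length(years) != 2 || years[2] < years[1])
    stop("`years` must be an inclusive year range", call. = FALSE)
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[2])), by = "day")
  nlat <- length(grid$lat); nlon <- length(grid$lon); nd <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  season <- scenario$seasonal_amp * cos(2 * pi * (doy - 196) / 365.2425)
  decades <- as.numeric(dates - dates[1]) / 3652.5
  cell_mean <- outer(t_base - lat_gradient * (grid$lat - min(grid$lat)),
                     rep(1, nlon))
  with_seed(seed, {
    tarr <- array(rnorm(nd * nlat * nlon, sd = scenario$noise_sd),
                  dim = c(nd, nlat, nlon))
    rarr <- array(rnorm(nd * nlat * nlon, sd = rh_noise_sd),
                  dim = c(nd, nlat, nlon))
    tarr <- tarr + rep(season + scenario$warming_rate * decades, nlat * nlon) +
      rep(cell_mean, each = nd)
    rarr <- rarr + rep(scenario$rh_mean + scenario$rh_trend * decades,
                       nlat * nlon)
    if (smooth) {
      for (d in seq_len(nd)) {
        tarr[d, , ] <- boxcar3(tarr[d, , , drop = TRUE], nlat, nlon)
        rarr[d, , ] <- boxcar3(rarr[d, , , drop = TRUE], nlat, nlon)
      }
    }
    rarr <- pmin(pmax(rarr, 0), 100)
    structure(list(dates = dates, lat = grid$lat, lon = grid$lon,
                   t = tarr, rh = rarr, scenario = scenario$name),
              class = "climate_grid")
  })
}

boxcar3 <- function(m, nr, nc) {
  m <- matrix(m, nr, nc)
  out <- m
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - 1):min(nr, i + 1)
    jj <- max(1, j - 1):min(nc, j + 1)
    out[i, j] <- mean(m[ii, jj])
  }
  out
}

#' Extract one cell of a climate grid as a climate series
#'
#' @param cg A `climate_grid` from [gen_climate()] or [read_climate()].
#' @param i,j Latitude and longitude cell indices.
#' @return A [climate_series()].
#' @export
cell_series <- function(cg, i, j) {
  stopifnot(inherits(cg, "climate_grid"))
  climate_series(cg$dates, cg$t[, i, j], cg$rh[, i, j])
}

#' Generate decadal gridded population
#'
#' Spatial weights are a fixed (seeded) smooth random surface; national
#' totals follow geometric growth per decade. Emulates decadal gridded
#' population projections.
#'
#' @param grid A [grid_def()].
#' @param base_total Persons nationally in the first decade; `> 0`.
#' @param decadal_growth Fractional growth per decade (`> -1`).
#' @param years Inclusive year range; a snapshot is produced for each
#'   decade start (multiples of 10) covering the range.
#' @param seed Integer seed.
#' @return Named list (by year) of `population_grid` objects: `year`,
#'   `lat`, `lon`, `res`, matrix `pop` (persons, `lat x lon`).
#' @export
gen_population <- function(grid, base_total, decadal_growth, years,
                           seed = 1L) {
  stopifnot(inherits(grid, "grid_def"), base_total > 0)
  if (decadal_growth <= -1)
    stop("`decadal_growth` must exceed -100%", call. = FALSE)
  decades <- seq(10 * floor(years[1] / 10), 10 * ceiling(years[2] / 10), 10)
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  w <- with_seed(seed, {
    w <- matrix(rgamma(nlat * nlon, shape = 2), nlat, nlon)
    boxcar3(w, nlat, nlon)
  })
  w <- w / sum(w)
  out <- lapply(seq_along(decades), function(k) {
    total <- base_total * (1 + decadal_growth)^(k - 1)
    structure(list(year = decades[k], lat = grid$lat, lon = grid$lon,
                   res = grid$res, pop = w * total),
              class = "population_grid")
  })
  names(out) <- decades
  out
}

#' Generate daily site mortality from a known lagged risk curve
#'
#' Counts are drawn with expected value
#' `baseline_rate * dow_effect * exp(sum_l w_l * logRR_true(HSI[i-l]))`
#' where `logRR_true` is the V-shaped curve of [true_log_rr()], with
#' variance `dispersion * mean` (Poisson when `dispersion = 1`, else
#' negative binomial), matching the quasi-Poisson assumption fitted
#' downstream. The first 21 days have incomplete lag history and are
#' returned with `NA` deaths.
#'
#' @param hsi Daily HSI series, degC (numeric vector); at least 22 days.
#' @param dates `Date` vector aligned with `hsi` (drives day-of-week).
#' @param truth A [true_risk_curve()].
#' @param baseline_rate Expected deaths/day at no heat effect; `> 0`.
#' @param dow_effects 7 multipliers, Monday first; default all 1.
#' @param dispersion Variance/mean ratio; `>= 1`.
#' @param seed Integer seed.
#' @param site_id,region_id Labels carried on the output.
#' @return A data frame of class `site_mortality` with columns `date`,
#'   `site_id`, `deaths` and attribute `region_id`.
#' @export
gen_site_mortality <- function(hsi, dates, truth, baseline_rate,
                               dow_effects = rep(1, 7), dispersion = 1,
                               seed = 1L, site_id = "site1",
                               region_id = "region1") {
  stopifnot(inherits(truth, "true_risk_curve"), length(hsi) == length(dates),
            length(dow_effects) == 7)
  if (length(hsi) < 22)
    stop("`hsi` must cover at least 22 days (21-day lag history)",
         call. = FALSE)
  if (baseline_rate <= 0) stop("`baseline_rate` must be > 0", call. = FALSE)
  if (dispersion < 1) stop("`dispersion` must be >= 1", call. = FALSE)
  n <- length(hsi)
  # lagged cumulative log RR: sum_l w_l * logRR_true(hsi[i - l])
  loglin <- stats::filter(true_log_rr(truth, hsi),
                          truth$lag_weights, sides = 1)
  dow_idx <- (as.integer(format(as.Date(dates), "%u")))  # 1 = Monday
  mu <- baseline_rate * dow_effects[dow_idx] * exp(as.numeric(loglin))
  ok <- !is.na(mu)
  deaths <- rep(NA_integer_, n)
  deaths[ok] <- with_seed(seed, {
    if (dispersion == 1) stats::rpois(sum(ok), mu[ok])
    else stats::rnbinom(sum(ok), mu = mu[ok],
                        size = mu[ok] / (dispersion - 1))
  })
  structure(data.frame(date = as.Date(dates), site_id = site_id,
                       deaths = deaths),
            region_id = region_id,
            class = c("site_mortality", "data.frame"))
}
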