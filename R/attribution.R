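# Heat-attributable mortality on the climate grid. Daily attributable
# deaths D = Mt * Pop * AF with AF = (RR - 1)/RR, summed over days whose
# HSI exceeds the regional minimum-mortality HSI; aggregation to regions,
# decades, and change ratios against the baseline period.

#' Attributable fraction from relative risk
#'
#' `AF = (RR - 1) / RR`, floored at 0 (only heat-risk days, where RR >= 1,
#' enter attribution; the floor is defensive).
#'
#' @param rr Relative risk, `> 0`. Vectorised.
#' @return Attributable fraction in `[0, 1)`.
#' @examples
#' af_from_rr(2)  # 0.5
#' @export
af_from_rr <- function(rr) {
  if (any(!is.na(rr) & rr <= 0)) stop("`rr` must be > 0", call. = FALSE)
  pmax(0, (rr - 1) / rr)
}

#' Annual heat-attributable deaths for one cell-year
#'
#' Sums `mt * pop * AF(RR(HSI_d))` over the days whose HSI exceeds the
#' curve's MMHSI; days at or below the MMHSI contribute zero. Cells missing
#' more than 10% of days are rejected.
#'
#' @param hsi_days Daily HSI for one cell and calendar year, degC.
#' @param curve The region's `er_curve` (with `mmhsi` set).
#' @param mt Baseline daily death rate per person.
#' @param pop Persons in the cell.
#' @return List with `hd` (attributable deaths) and `heat_days` (count of
#'   days above the MMHSI).
#' @export
annual_heat_deaths <- function(hsi_days, curve, mt, pop) {
  stopifnot(inherits(curve, "er_curve"), mt >= 0, pop >= 0)
  n_na <- sum(is.na(hsi_days))
  if (n_na > 0.1 * length(hsi_days))
    stop("more than 10% of days missing; cell excluded", call. = FALSE)
  hot <- !is.na(hsi_days) & hsi_days > curve$mmhsi
  if (!any(hot)) return(list(hd = 0, heat_days = 0L))
  rr <- rr_at(curve, hsi_days[hot], extrapolate = TRUE)$rr
  list(hd = sum(mt * pop * af_from_rr(rr)), heat_days = sum(hot))
}

#' Aggregate cell attributable deaths to regions
#'
#' `Reg_HD = sum(hd)` over the region's cells (exact) and
#' `Reg_HM = Reg_HD / sum(pop)`, reported per mille. Regions with zero
#' population get `NA` rates.
#'
#' @param hd Matrix of annual attributable deaths per cell (`lat x lon`).
#' @param region_mask Matrix of region labels aligned with `hd`; `NA`
#'   cells are outside every region.
#' @param pop Matrix of persons per cell aligned with `hd`.
#' @return Data frame with `region`, `hd`, `pop`, `hm_permille`.
#' @export
regional_aggregate <- function(hd, region_mask, pop) {
  stopifnot(all(dim(hd) == dim(region_mask)), all(dim(hd) == dim(pop)))
  regions <- sort(unique(stats::na.omit(as.vector(region_mask))))
  out <- do.call(rbind, lapply(regions, function(r) {
    sel <- !is.na(region_mask) & region_mask == r
    hd_r <- sum(hd[sel], na.rm = TRUE)
    pop_r <- sum(pop[sel], na.rm = TRUE)
    data.frame(region = r, hd = hd_r, pop = pop_r,
               hm_permille = if (pop_r > 0) 1000 * hd_r / pop_r else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Decadal means and change ratios against the baseline
#'
#' Arithmetic means of an annual series within each decade window (half-open
#' `[y0, y0 + 10)`) and within the baseline window, plus the change ratio
#' `future_mean / baseline_mean * 100` in percent.
#'
#' @param years Integer vector of years.
#' @param values Annual values aligned with `years` (e.g. `Reg_HM`).
#' @param windows Named list of decade start years, default the 2030s-2090s.
#' @param baseline Length-2 inclusive baseline year range, default
#'   `c(1995, 2014)`.
#' @return Data frame with `window`, `mean`, `ratio_pct` (the baseline row
#'   has ratio 100). Windows with no covered years are dropped with a
#'   warning; partially covered windows warn.
#' @export
decadal_summary <- function(years, values,
                            windows = as.list(stats::setNames(
                              seq(2030, 2090, 10),
                              paste0(seq(2030, 2090, 10), "s"))),
                            baseline = c(1995, 2014)) {
  stopifnot(length(years) == length(values))
  base_sel <- years >= baseline[1] & years <= baseline[2]
  if (!any(base_sel)) stop("no years in the baseline window", call. = FALSE)
  if (sum(base_sel) < diff(baseline) + 1)
    warning("baseline window only partially covered", call. = FALSE)
  base_mean <- mean(values[base_sel], na.rm = TRUE)
  rows <- list(data.frame(window = "baseline", mean = base_mean,
                          ratio_pct = 100))
  for (nm in names(windows)) {
    y0 <- windows[[nm]]
    sel <- years >= y0 & years < y0 + 10   # half-open decade
    if (!any(sel)) { warning("window ", nm, " not covered; dropped",
                             call. = FALSE); next }
    if (sum(sel) < 10)
      warning("window ", nm, " only partially covered", call. = FALSE)
    m <- mean(values[sel], na.rm = TRUE)
    rows[[length(rows) + 1]] <-
      data.frame(window = nm, mean = m, ratio_pct = 100 * m / base_mean)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Regrid a fine population grid to a coarser resolution
#'
#' Bilinear interpolation of population density at the coarse cell centres,
#' rescaled so the total is conserved (to well under 0.1%). Intended for
#' 0.125 deg to 0.25 deg regridding of decadal population onto the climate
#' grid.
#'
#' @param pop_fine A `population_grid` (fields `lat`, `lon`, `res`, `pop`).
#' @param res_out Target resolution in degrees; default twice the input.
#' @return A `population_grid` at the coarse resolution covering the same
#'   extent.
#' @export
regrid_population <- function(pop_fine, res_out = 2 * pop_fine$res) {
  stopifnot(inherits(pop_fine, "population_grid"))
  if (res_out <= pop_fine$res)
    stop("target grid must be coarser than the source", call. = FALSE)
  res_in <- pop_fine$res
  lat_f <- pop_fine$lat; lon_f <- pop_fine$lon
  ext_lat <- c(min(lat_f) - res_in / 2, max(lat_f) + res_in / 2)
  ext_lon <- c(min(lon_f) - res_in / 2, max(lon_f) + res_in / 2)
  g <- grid_def(ext_lat, ext_lon, res_out)
  dens <- pop_fine$pop / res_in^2
  interp1 <- function(centres, x) {
    # index pairs and weights for linear interpolation, clamped at edges
    i <- findInterval(x, centres, all.inside = TRUE)
    i <- pmin(pmax(i, 1), length(centres) - 1)
    w <- (x - centres[i]) / (centres[i + 1] - centres[i])
    w <- pmin(pmax(w, 0), 1)
    list(i = i, w = w)
  }
  ia <- interp1(lat_f, g$lat)
  io <- interp1(lon_f, g$lon)
  out <- matrix(0, length(g$lat), length(g$lon))
  for (a in seq_along(g$lat)) for (o in seq_along(g$lon)) {
    i <- ia$i[a]; wa <- ia$w[a]; j <- io$i[o]; wo <- io$w[o]
    d <- (1 - wa) * (1 - wo) * dens[i, j] +
         wa * (1 - wo) * dens[i + 1, j] +
         (1 - wa) * wo * dens[i, j + 1] +
         wa * wo * dens[i + 1, j + 1]
    out[a, o] <- d * res_out^2
  }
  total_in <- sum(pop_fine$pop)
  total_out <- sum(out)
  if (total_out > 0) out <- out * (total_in / total_out)
  structure(list(year = pop_fine$year, lat = g$lat, lon = g$lon,
                 res = res_out, pop = out),
            class = "population_grid")
}

#' Regional minimum-mortality HSI reference configuration
#'
#' A documented example configuration of regional minimum-mortality HSI
#' values (degC) for the seven Chinese climatic subregions - Northeast
#' (NE), North (NC), Northwest (NW), East (EC), Central (CC), Southwest
#' (SW) and South (SC) China - as estimated from surveillance-site curves
#' in the heat-mortality literature this pipeline emulates. Shipped as a
#' ready-made attribution config for illustration; it is not recomputed by
#' the package.
#'
#' @return Named numeric vector of MMHSI in degC.
#' @export
mmhsi_regions_cn <- function() {
  c(NE = 24, NC = 26, NW = 25, EC = 25, CC = 35, SW = 29, SC = 32)
}
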