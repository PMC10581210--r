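# Formats, configuration and orchestration. Gridded fields travel as
# long-format CSV (date/lat/lon plus variable columns) with unit
# auto-detection on read; curves are serialized to JSON; every output
# carries the run's config hash so mixed-provenance inputs are refused.

#' Write gridded daily climate to long-format CSV
#'
#' Columns `date`, `lat`, `lon`, `tas` (degC or K per `kelvin`), `hurs`
#' (percent).
#'
#' @param cg A `climate_grid`.
#' @param path Output CSV path.
#' @param kelvin Write temperature in Kelvin (default `FALSE`: degC).
#' @return `path`, invisibly.
#' @export
write_climate <- function(cg, path, kelvin = FALSE) {
  stopifnot(inherits(cg, "climate_grid"))
  nd <- length(cg$dates)
  grid <- expand.grid(date = format(cg$dates, "%Y-%m-%d"),
                      lat = cg$lat, lon = cg$lon,
                      stringsAsFactors = FALSE)
  tas <- as.vector(cg$t) + if (kelvin) 273.15 else 0
  utils::write.csv(data.frame(grid, tas = tas, hurs = as.vector(cg$rh)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read gridded daily climate from long-format CSV
#'
#' Expects columns `date`, `lat`, `lon`, and temperature / relative
#' humidity columns named `tas` and `hurs` (or `t` / `rh`). Units are
#' normalised: temperatures whose median exceeds 150 are treated as Kelvin
#' and converted to degC; humidity with maximum at or below 1.5 is treated
#' as a fraction and converted to percent.
#'
#' @param path CSV file path.
#' @return A `climate_grid`.
#' @export
read_climate <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tcol <- intersect(c("tas", "t"), names(df))[1]
  rcol <- intersect(c("hurs", "rh"), names(df))[1]
  miss <- c(setdiff(c("date", "lat", "lon"), names(df)),
            if (is.na(tcol)) "tas", if (is.na(rcol)) "hurs")
  if (length(miss))
    stop("climate CSV lacks column(s): ", paste(miss, collapse = ", "),
         "; expected date, lat, lon, tas (or t), hurs (or rh)",
         call. = FALSE)
  tas <- df[[tcol]]
  if (stats::median(tas, na.rm = TRUE) > 150) tas <- tas - 273.15
  hurs <- df[[rcol]]
  if (max(hurs, na.rm = TRUE) <= 1.5) hurs <- 100 * hurs
  dates <- sort(unique(as.Date(df$date)))
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  ord <- order(match(df$lon, lon), match(df$lat, lat),
               match(as.Date(df$date), dates))
  dimn <- c(length(dates), length(lat), length(lon))
  structure(list(dates = dates, lat = lat, lon = lon,
                 t = array(tas[ord], dim = dimn),
                 rh = array(hurs[ord], dim = dimn),
                 scenario = NA_character_),
            class = "climate_grid")
}

#' Write / read decadal population grids as CSV
#'
#' Long format with columns `year`, `lat`, `lon`, `pop`.
#'
#' @param pops Named list of `population_grid`s (as from
#'   [gen_population()]).
#' @param path CSV path.
#' @return `write_population`: `path` invisibly; `read_population`: a named
#'   list of `population_grid`s.
#' @export
write_population <- function(pops, path) {
  rows <- do.call(rbind, lapply(pops, function(p) {
    data.frame(expand.grid(lat = p$lat, lon = p$lon), year = p$year,
               pop = as.vector(p$pop), res = p$res)
  }))
  utils::write.csv(rows[c("year", "lat", "lon", "pop", "res")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  df <- utils::read.csv(path)
  out <- lapply(split(df, df$year), function(d) {
    lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
    ord <- order(match(d$lon, lon), match(d$lat, lat))
    structure(list(year = d$year[1], lat = lat, lon = lon, res = d$res[1],
                   pop = matrix(d$pop[ord], length(lat), length(lon))),
              class = "population_grid")
  })
  names(out) <- vapply(out, function(p) as.character(p$year), "")
  out
}

#' Serialize / load regional exposure-response curves
#'
#' JSON container holding each region's basis definition, reduced
#' coefficients and covariance, MMHSI, and the producing run's config hash.
#' `read_curves()` refuses a file whose hash does not match `expect_hash`.
#'
#' @param curves Named list of `er_curve`s (by region).
#' @param path JSON path.
#' @param config_hash Hash string stamped into the file.
#' @param expect_hash If non-`NULL`, required hash on read.
#' @return `write_curves`: `path` invisibly; `read_curves`: named list of
#'   `er_curve`s with attribute `config_hash`.
#' @export
write_curves <- function(curves, path, config_hash = "") {
  payload <- list(config_hash = config_hash,
                  curves = lapply(curves, function(cv) {
                    list(region_id = cv$region_id,
                         exposure_knots = cv$exposure_knots,
                         exposure_boundary = cv$exposure_boundary,
                         exposure_df = cv$exposure_df,
                         coef = cv$coef, vcov = cv$vcov,
                         mmhsi = cv$mmhsi, hsi_range = cv$hsi_range)
                  }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path, expect_hash = NULL) {
  if (!file.exists(path))
    stop("curve file not found: ", path,
         " (run the fitting/pooling stage first)", call. = FALSE)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(expect_hash) && !identical(payload$config_hash, expect_hash))
    stop("curve file was produced under a different configuration ",
         "(config hash mismatch); refusing mixed-provenance inputs",
         call. = FALSE)
  curves <- lapply(payload$curves, function(cv) {
    spec <- list(exposure_knots = cv$exposure_knots,
                 exposure_boundary = cv$exposure_boundary,
                 exposure_df = cv$exposure_df)
    new_er_curve(spec, cv$coef, matrix(unlist(cv$vcov), cv$exposure_df),
                 cv$hsi_range, mmhsi = cv$mmhsi, region_id = cv$region_id)
  })
  attr(curves, "config_hash") <- payload$config_hash
  curves
}

#' Pipeline run configuration
#'
#' Bundles every knob of a full synthetic-data pipeline run. The defaults
#' describe the demonstration problem (a 5 x 5 cell grid, 3 surveillance
#' sites, 2 scenarios, 2 pseudo-models, 100 Monte Carlo draws) sized to run
#' in seconds-to-minutes on one CPU.
#'
#' @param grid A [grid_def()].
#' @param scenarios List of [scenario_spec()]s.
#' @param n_models Pseudo-models per scenario (climate noise realisations).
#' @param years_baseline,years_future Inclusive year ranges; must be
#'   disjoint.
#' @param n_sites Number of surveillance sites to simulate and fit.
#' @param truth [true_risk_curve()] generating site mortality.
#' @param baseline_rate Site baseline deaths/day.
#' @param mt Baseline daily death rate per person for attribution.
#' @param pop_total,pop_growth National population and decadal growth.
#' @param spec [crossbasis_spec()] for the site models.
#' @param draws Monte Carlo draws per model (`> 0` requires `seed`).
#' @param seed Master seed for every random stage.
#' @param hsi_mode `"nws"` or `"celsius"` (see [heat_index()]).
#' @param out_dir Output directory.
#' @return A `run_config` list with a `hash` field (outputs are stamped
#'   with it; `out_dir` does not enter the hash).
#' @export
run_config <- function(grid = grid_def(c(25, 26.25), c(110, 111.25), 0.25),
                       scenarios = default_scenarios()[c("ssp126", "ssp585")],
                       n_models = 2,
                       years_baseline = c(1995, 2004),
                       years_future = c(2030, 2049),
                       n_sites = 3,
                       truth = true_risk_curve(),
                       baseline_rate = 30,
                       mt = 2e-5,
                       pop_total = 1e6, pop_growth = 0.05,
                       spec = crossbasis_spec(),
                       draws = 100, seed = 1L,
                       hsi_mode = "nws",
                       out_dir = tempfile("heatmort_run")) {
  if (years_baseline[2] >= years_future[1])
    stop("baseline and future windows must be disjoint", call. = FALSE)
  if (draws > 0 && is.null(seed))
    stop("`seed` must be set when draws > 0", call. = FALSE)
  cfg <- list(grid = grid, scenarios = scenarios, n_models = n_models,
              years_baseline = years_baseline, years_future = years_future,
              n_sites = n_sites, truth = truth,
              baseline_rate = baseline_rate, mt = mt,
              pop_total = pop_total, pop_growth = pop_growth, spec = spec,
              draws = draws, seed = as.integer(seed), hsi_mode = hsi_mode,
              out_dir = out_dir)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

# Population interpolated linearly in time between decadal snapshots.
pop_at_year <- function(pops, year) {
  yrs <- as.numeric(names(pops))
  if (year <= min(yrs)) return(pops[[which.min(yrs)]]$pop)
  if (year >= max(yrs)) return(pops[[which.max(yrs)]]$pop)
  i <- findInterval(year, yrs)
  w <- (year - yrs[i]) / (yrs[i + 1] - yrs[i])
  (1 - w) * pops[[i]]$pop + w * pops[[i + 1]]$pop
}

# Per-draw annual attributable deaths for one cell-year: shared basis work
# across draws keeps the Monte Carlo loop a single matrix product.
hd_per_draw <- function(hsi_days, curve, draws, mt, pop) {
  hot <- !is.na(hsi_days) & hsi_days > curve$mmhsi
  if (!any(hot)) return(rep(0, nrow(draws)))
  d <- curve_basis(curve, hsi_days[hot]) -
    matrix(curve_basis(curve, curve$mmhsi), sum(hot),
           curve$exposure_df, byrow = TRUE)
  eta <- d %*% t(draws)                      # hot days x draws
  af <- matrix(pmax(0, 1 - exp(-eta)), nrow(eta))  # (rr-1)/rr = 1 - 1/rr
  mt * pop * colSums(af)
}

#' Run the full synthetic-data pipeline
#'
#' Orchestrates all stages in order: synthetic climate per scenario and
#' pseudo-model, HSI grids, site mortality simulation and DLNM fits on the
#' baseline climate, regional pooling (REML + BLUP), attributable-death
#' projection over the future climate with decadal change ratios against
#' the baseline, Monte Carlo + ensemble envelopes, and the
#' temperature/humidity driver decomposition. Deterministic given
#' (config, seed); all outputs carry the config hash.
#'
#' Files written to `config$out_dir`: `hsi_annual.csv` (per-cell annual
#' mean HSI), `curves.json`, `sites.csv`, `attribution_annual.csv`,
#' `attribution_decadal.csv` (with envelope columns `lo`, `hi`),
#' `drivers.csv`, and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory results: `curves`,
#'   `annual`, `decadal`, `drivers`, `paths`, `config_hash`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  grid <- config$grid
  all_years <- c(config$years_baseline[1], config$years_future[2])
  scen_names <- vapply(config$scenarios, `[[`, "", "name")

  # --- climate + HSI ------------------------------------------------------
  message("stage climate/hsi: ", length(scen_names), " scenario(s) x ",
          config$n_models, " model(s)")
  clim <- list(); hsi <- list()
  hsi_rows <- list()
  for (s in seq_along(config$scenarios)) {
    for (m in seq_len(config$n_models)) {
      key <- paste(scen_names[s], m, sep = ".")
      cg <- gen_climate(grid, config$scenarios[[s]], all_years,
                        seed = config$seed + 1000L * s + m)
      h <- heat_index_series(cg, mode = config$hsi_mode)
      clim[[key]] <- cg; hsi[[key]] <- h
      yr <- as.integer(format(cg$dates, "%Y"))
      for (y in unique(yr)) {
        hm_y <- apply(h[yr == y, , , drop = FALSE], c(2, 3), mean)
        hsi_rows[[length(hsi_rows) + 1]] <- data.frame(
          scenario = scen_names[s], model = m, year = y,
          expand.grid(lat = cg$lat, lon = cg$lon),
          hsi_mean = as.vector(hm_y))
      }
    }
  }
  hsi_annual <- do.call(rbind, hsi_rows)
  hsi_annual$config_hash <- config$hash
  utils::write.csv(hsi_annual, file.path(config$out_dir, "hsi_annual.csv"),
                   row.names = FALSE)

  # --- sites: simulate, fit, pool ----------------------------------------
  message("stage fit/pool: ", config$n_sites, " site(s)")
  base_key <- paste(scen_names[1], 1, sep = ".")
  cg0 <- clim[[base_key]]; h0 <- hsi[[base_key]]
  base_sel <- as.integer(format(cg0$dates, "%Y")) <= config$years_baseline[2]
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  cells <- with_seed(config$seed + 77L,
                     sample(nlat * nlon, config$n_sites))
  site_hsi_pool <- unlist(lapply(cells, function(cl) {
    ij <- arrayInd(cl, c(nlat, nlon))
    h0[base_sel, ij[1], ij[2]]
  }))
  spec <- resolve_spec(config$spec, site_hsi_pool)  # shared basis
  fits <- list(); sites <- list()
  for (k in seq_along(cells)) {
    ij <- arrayInd(cells[k], c(nlat, nlon))
    hsi_site <- h0[base_sel, ij[1], ij[2]]
    site <- gen_site_mortality(hsi_site, cg0$dates[base_sel], config$truth,
                               config$baseline_rate,
                               seed = config$seed + 500L + k,
                               site_id = sprintf("site%02d", k),
                               region_id = "R1")
    fits[[k]] <- fit_site_model(site, hsi_site, spec)
    sites[[k]] <- site
  }
  write_mortality(sites, file.path(config$out_dir, "sites.csv"))
  rp <- pool(lapply(fits, reduce_overall), region_id = "R1")
  curves <- list(R1 = region_curve(rp))
  curves_path <- file.path(config$out_dir, "curves.json")
  write_curves(curves, curves_path, config_hash = config$hash)

  # --- projection + uncertainty + drivers --------------------------------
  res <- run_project(config, curves_path, clim = clim, hsi = hsi)
  manifest <- list(config_hash = config$hash, seed = config$seed,
                   package_version = as.character(
                     utils::packageVersion("heatmort")),
                   scenarios = scen_names, n_models = config$n_models,
                   files = basename(res$paths))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(res, list(curves = curves, config_hash = config$hash)))
}

#' Projection stage: attribution, envelopes, drivers from stored curves
#'
#' Reads the regional curves produced by the fitting stage (refusing a
#' curve file from a different configuration) and projects annual and
#' decadal heat-attributable mortality with Monte Carlo + ensemble
#' envelopes and the driver decomposition. Called by [run_pipeline()];
#' callable alone against an existing curve file.
#'
#' @param config A [run_config()].
#' @param curves_path Path to `curves.json`.
#' @param clim,hsi Optional precomputed climate/HSI lists (internal reuse);
#'   regenerated from the config when `NULL`.
#' @return List with `annual`, `decadal`, `drivers` data frames and
#'   `paths`.
#' @export
run_project <- function(config, curves_path, clim = NULL, hsi = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  curves <- read_curves(curves_path, expect_hash = config$hash)
  grid <- config$grid
  scen_names <- vapply(config$scenarios, `[[`, "", "name")
  nlat <- length(grid$lat); nlon <- length(grid$lon)
  if (is.null(clim)) {
    clim <- list(); hsi <- list()
    for (s in seq_along(config$scenarios)) for (m in seq_len(config$n_models)) {
      key <- paste(scen_names[s], m, sep = ".")
      cg <- gen_climate(grid, config$scenarios[[s]],
                        c(config$years_baseline[1], config$years_future[2]),
                        seed = config$seed + 1000L * s + m)
      clim[[key]] <- cg
      hsi[[key]] <- heat_index_series(cg, mode = config$hsi_mode)
    }
  }
  pops <- gen_population(grid, config$pop_total, config$pop_growth,
                         c(config$years_baseline[1], config$years_future[2]),
                         seed = config$seed + 11L)
  curve <- curves[["R1"]]
  mask <- matrix("R1", nlat, nlon)

  message("stage project: attribution over ", length(scen_names),
          " scenario(s)")
  annual_rows <- list(); dec_rows <- list(); drv_rows <- list()
  for (s in seq_along(config$scenarios)) {
    per_model_annual <- list()
    drv_feat <- list()
    for (m in seq_len(config$n_models)) {
      key <- paste(scen_names[s], m, sep = ".")
      cg <- clim[[key]]; h <- hsi[[key]]
      yr <- as.integer(format(cg$dates, "%Y"))
      years <- unique(yr)
      draws <- if (config$draws > 0)
        sample_coefficients(curve, config$draws,
                            seed = config$seed + 104729L * (100 * s + m))
      else NULL
      for (y in years) {
        sel <- yr == y
        popm <- pop_at_year(pops, y)
        hd_cells <- matrix(0, nlat, nlon)
        hd_draw_tot <- if (!is.null(draws)) rep(0, nrow(draws)) else NULL
        for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
          hd_cells[i, j] <- annual_heat_deaths(
            h[sel, i, j], curve, config$mt, popm[i, j])$hd
          if (!is.null(draws))
            hd_draw_tot <- hd_draw_tot +
              hd_per_draw(h[sel, i, j], curve, draws, config$mt, popm[i, j])
        }
        agg <- regional_aggregate(hd_cells, mask, popm)
        annual_rows[[length(annual_rows) + 1]] <- data.frame(
          scenario = scen_names[s], model = m, region = "R1", year = y,
          hd = agg$hd, hm_permille = agg$hm_permille)
        per_model_annual[[length(per_model_annual) + 1]] <- data.frame(
          model = m, year = y, hd = agg$hd,
          hm = agg$hm_permille, pop = agg$pop,
          draws_hm = if (!is.null(draws))
            I(list(1000 * hd_draw_tot / agg$pop)) else I(list(NULL)))
        # driver features: heat-day means per cell (future years only)
        if (y >= config$years_future[1]) {
          hm_cell <- 1000 * hd_cells / popm
          drv_feat[[length(drv_feat) + 1]] <- driver_rows_year(
            cg$t[sel, , , drop = FALSE], cg$rh[sel, , , drop = FALSE],
            h[sel, , , drop = FALSE], hm_cell, popm, curve$mmhsi)
        }
      }
    }
    pm <- do.call(rbind, per_model_annual)
    wins <- decade_windows(config$years_future)
    base_years <- config$years_baseline
    for (w in c("baseline", names(wins))) {
      sel <- if (w == "baseline") pm$year >= base_years[1] &
               pm$year <= base_years[2]
             else pm$year >= wins[[w]] & pm$year < wins[[w]] + 10
      if (!any(sel)) next
      mean_hm <- mean(vapply(split(pm$hm[sel], pm$model[sel]), mean, 0))
      env <- if (config$draws > 0) {
        by_model <- lapply(split(pm[sel, ], pm$model[sel]), function(d) {
          rowMeans(do.call(cbind, d$draws_hm))
        })
        ensemble_envelope(by_model)
      } else NULL
      dec_rows[[length(dec_rows) + 1]] <- data.frame(
        scenario = scen_names[s], region = "R1", window = w,
        hm_permille = mean_hm,
        lo = if (!is.null(env)) env$lo else NA_real_,
        hi = if (!is.null(env)) env$hi else NA_real_)
    }
    drv <- do.call(rbind, drv_feat)
    if (!is.null(drv) && nrow(drv) >= 30 && stats::sd(drv$hm) > 0) {
      drv_rows[[length(drv_rows) + 1]] <- gini_contributions(
        drv, seed = config$seed + 13L, region_id = "R1",
        scenario = scen_names[s])
    }
  }
  annual <- do.call(rbind, annual_rows)
  dec <- do.call(rbind, dec_rows)
  dec$ratio_pct <- NA_real_
  for (sc in unique(dec$scenario)) {
    b <- dec$hm_permille[dec$scenario == sc & dec$window == "baseline"]
    if (length(b) == 1 && is.finite(b) && b > 0)
      dec$ratio_pct[dec$scenario == sc] <-
        100 * dec$hm_permille[dec$scenario == sc] / b
  }
  drivers <- if (length(drv_rows)) do.call(rbind, drv_rows) else NULL
  annual$config_hash <- config$hash
  dec$config_hash <- config$hash
  paths <- file.path(config$out_dir,
                     c("attribution_annual.csv", "attribution_decadal.csv",
                       "drivers.csv", "curves.json", "hsi_annual.csv",
                       "sites.csv", "manifest.json"))
  utils::write.csv(annual, paths[1], row.names = FALSE)
  utils::write.csv(dec, paths[2], row.names = FALSE)
  if (!is.null(drivers)) {
    drivers$config_hash <- config$hash
    utils::write.csv(drivers, paths[3], row.names = FALSE)
  }
  list(annual = annual, decadal = dec, drivers = drivers, paths = paths)
}

# Decade windows (starts) fully covered by the future year range.
decade_windows <- function(years_future) {
  starts <- seq(10 * ceiling(years_future[1] / 10),
                10 * floor((years_future[2] - 9) / 10), by = 10)
  starts <- starts[starts >= years_future[1] &
                     starts + 9 <= years_future[2]]
  as.list(stats::setNames(starts, paste0(starts, "s")))
}

# Driver feature rows for one year: per-cell heat-day mean T/RH + hm.
driver_rows_year <- function(tarr, rharr, harr, hm_cell, popm, mmhsi) {
  nlat <- dim(tarr)[2]; nlon <- dim(tarr)[3]
  rows <- list()
  for (i in seq_len(nlat)) for (j in seq_len(nlon)) {
    if (popm[i, j] <= 0) next
    hot <- !is.na(harr[, i, j]) & harr[, i, j] > mmhsi
    if (!any(hot)) next
    rows[[length(rows) + 1]] <- data.frame(
      t_mean = mean(tarr[hot, i, j]), rh_mean = mean(rharr[hot, i, j]),
      hm = hm_cell[i, j])
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
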