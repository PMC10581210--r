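# Temperature-versus-humidity driver decomposition: random-forest Gini
# (variance-reduction) importance of heat-day mean temperature and relative
# humidity for annual heat-attributable mortality, scaled to percent shares.

#' Feature/target table for driver decomposition
#'
#' One row per inhabited cell-year: mean temperature and mean relative
#' humidity over the days whose HSI exceeds the regional MMHSI, with the
#' annual heat-related mortality rate as target. Cell-years with no heat
#' days and cells with zero population are dropped.
#'
#' @param t_daily,rh_daily,hsi_daily Numeric `day x cell` matrices for one
#'   year (columns are cells), or lists of such matrices (one per year).
#' @param hm Annual heat-related mortality per cell (vector per year, or
#'   list of vectors aligned with the matrices).
#' @param pop Persons per cell (vector; cells with 0 are excluded).
#' @param mmhsi Heat-day threshold, degC (scalar or per-cell vector).
#' @return Data frame with `cell`, `year`, `t_mean`, `rh_mean`, `hm`.
#' @export
driver_table <- function(t_daily, rh_daily, hsi_daily, hm, pop, mmhsi) {
  if (is.matrix(t_daily)) {
    t_daily <- list(t_daily); rh_daily <- list(rh_daily)
    hsi_daily <- list(hsi_daily); hm <- list(hm)
  }
  stopifnot(length(t_daily) == length(rh_daily),
            length(t_daily) == length(hsi_daily),
            length(t_daily) == length(hm))
  n_cell <- ncol(t_daily[[1]])
  mmhsi <- rep_len(mmhsi, n_cell)
  rows <- list()
  for (y in seq_along(t_daily)) {
    for (cl in seq_len(n_cell)) {
      if (pop[cl] <= 0) next
      hot <- !is.na(hsi_daily[[y]][, cl]) & hsi_daily[[y]][, cl] > mmhsi[cl]
      if (!any(hot)) next
      rows[[length(rows) + 1]] <- data.frame(
        cell = cl, year = y,
        t_mean = mean(t_daily[[y]][hot, cl]),
        rh_mean = mean(rh_daily[[y]][hot, cl]),
        hm = hm[[y]][cl])
    }
  }
  if (!length(rows))
    stop("no inhabited cell-years with heat days remain after filtering",
         call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Temperature and humidity contribution shares by Gini importance
#'
#' Fits a regression random forest (variance-reduction impurity) of the
#' heat-related mortality rate on heat-day mean temperature and relative
#' humidity, and scales the two Gini importances to sum to 100%.
#'
#' @param table Data frame from [driver_table()] (columns `t_mean`,
#'   `rh_mean`, `hm`); at least 30 rows.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed (forest bootstrap is randomised).
#' @param region_id,scenario Labels carried to the output.
#' @return A `driver_contribution` data frame with `region_id`, `scenario`,
#'   `temp_share` and `hum_share` (percent, summing to 100).
#' @export
gini_contributions <- function(table, n_trees = 500, seed = 1L,
                               region_id = NA_character_,
                               scenario = NA_character_) {
  stopifnot(all(c("t_mean", "rh_mean", "hm") %in% names(table)))
  if (nrow(table) < 30)
    stop("driver decomposition needs at least 30 cell-year rows",
         call. = FALSE)
  if (stats::sd(table$hm) == 0)
    stop("constant mortality target; importances undefined", call. = FALSE)
  rf <- with_seed(seed,
    randomForest::randomForest(hm ~ t_mean + rh_mean, data = table,
                               ntree = n_trees, mtry = 2))
  imp <- randomForest::importance(rf, type = 2)[, 1]
  shares <- 100 * imp / sum(imp)
  structure(data.frame(region_id = region_id, scenario = scenario,
                       temp_share = unname(shares["t_mean"]),
                       hum_share = unname(shares["rh_mean"])),
            class = c("driver_contribution", "data.frame"))
}
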