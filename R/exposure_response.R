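# First-stage site-level modelling: quasi-Poisson DLNM regression of daily
# deaths on the HSI cross-basis, with a natural cubic spline of time
# (7 df/year) for seasonality/trend and day-of-week indicators; reduction of
# the fitted surface to the overall cumulative exposure-response curve and
# location of the minimum-mortality HSI (MMHSI).

#' Fit the site-level distributed lag nonlinear model
#'
#' Quasi-Poisson GLM (log link) of daily deaths on intercept + HSI
#' cross-basis + natural cubic spline of time (`time_df_per_year` df per
#' year) + six day-of-week indicators (contrasts against Monday). Rows with
#' incomplete 21-day lag history or missing deaths are dropped from the
#' likelihood. The covariance is scaled by the Pearson chi-square / df
#' dispersion estimate.
#'
#' @param site A `site_mortality` data frame (`date`, `site_id`, `deaths`)
#'   from [gen_site_mortality()] or [read_mortality()].
#' @param hsi Daily HSI vector, degC, aligned with `site$date`.
#' @param spec A [crossbasis_spec()]; data-dependent knots resolved against
#'   this site's HSI unless fixed in the spec (fix them when fits are to be
#'   pooled, so all sites share one basis).
#' @param time_df_per_year Df per year for the seasonality/trend spline
#'   (default 7).
#' @param dow Include day-of-week indicators (default `TRUE`).
#' @return A `site_fit` list: cross-basis coefficients `coef`, their
#'   dispersion-scaled covariance `vcov`, `dispersion`, `converged`,
#'   `n_days`, the resolved `spec`, observed `hsi_range` and percentile
#'   table `hsi_q`, and `site_id` / `region_id` labels.
#' @export
fit_site_model <- function(site, hsi, spec = crossbasis_spec(),
                           time_df_per_year = 7, dow = TRUE) {
  stopifnot(is.data.frame(site), all(c("date", "deaths") %in% names(site)),
            length(hsi) == nrow(site))
  deaths <- site$deaths
  if (all(is.na(deaths) | deaths == 0))
    stop("all-zero death series cannot be fitted", call. = FALSE)
  n_years <- as.numeric(diff(range(site$date))) / 365.25
  if (n_years < 2)
    warning("less than 2 years of data; estimates may be unstable",
            call. = FALSE)
  cb <- build_crossbasis(hsi, spec)
  spec <- attr(cb, "spec")
  tns <- splines::ns(seq_len(nrow(site)),
                     df = max(2, round(time_df_per_year * n_years)))
  dat <- data.frame(deaths = deaths)
  X <- cbind(cb, tns)
  colnames(X) <- c(colnames(cb), paste0("time", seq_len(ncol(tns))))
  if (dow) {
    dowf <- factor(format(as.Date(site$date), "%u"), levels = as.character(1:7))
    D <- stats::model.matrix(~dowf)[, -1, drop = FALSE]
    colnames(D) <- paste0("dow", 2:7)
    X <- cbind(X, D)
  }
  keep <- stats::complete.cases(X) & !is.na(deaths)
  fit <- stats::glm(deaths[keep] ~ X[keep, , drop = FALSE],
                    family = stats::quasipoisson())
  if (!fit$converged)
    warning("site model did not converge; flagging fit", call. = FALSE)
  sm <- summary(fit)
  cb_idx <- seq_len(ncol(cb)) + 1L  # after intercept
  co <- stats::coef(fit)[cb_idx]
  V <- sm$cov.scaled[cb_idx, cb_idx, drop = FALSE]
  names(co) <- colnames(cb)
  hsi_obs <- hsi[keep]
  structure(list(
    coef = co, vcov = (V + t(V)) / 2, dispersion = sm$dispersion,
    converged = fit$converged, n_days = sum(keep), spec = spec,
    hsi_range = range(hsi_obs, na.rm = TRUE),
    hsi_obs = hsi_obs,
    site_id = site$site_id[1],
    region_id = attr(site, "region_id") %||% NA_character_
  ), class = "site_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reduce a fitted DLNM to the overall cumulative exposure-response curve
#'
#' Sums the lag-basis contributions over lags 0-21 into one coefficient per
#' exposure-basis function, with covariance propagated as `B V B'` for the
#' (linear) reduction matrix `B`, then centres the curve at its
#' minimum-mortality HSI so that `RR(mmhsi) = 1`.
#'
#' @param fit A `site_fit` from [fit_site_model()].
#' @param mmhsi_window Search window for the MMHSI as percentiles of the
#'   observed site HSI (default 1st-99th).
#' @return An `er_curve`: exposure basis definition, reduced coefficients
#'   `coef` and covariance `vcov`, `mmhsi` (degC) and `hsi_range`.
#' @export
reduce_overall <- function(fit, mmhsi_window = c(0.01, 0.99)) {
  stopifnot(inherits(fit, "site_fit"))
  if (!fit$converged) stop("cannot reduce a non-converged fit", call. = FALSE)
  B <- reduction_matrix(fit$spec)
  co <- drop(B %*% fit$coef)
  V <- B %*% fit$vcov %*% t(B)
  curve <- new_er_curve(fit$spec, co, V, fit$hsi_range,
                        region_id = fit$region_id)
  win <- unname(stats::quantile(fit$hsi_obs, mmhsi_window, na.rm = TRUE))
  curve$mmhsi <- find_mmhsi(curve, window = win)
  curve
}

new_er_curve <- function(spec, coef, vcov, hsi_range, mmhsi = NA_real_,
                         region_id = NA_character_) {
  structure(list(exposure_knots = spec$exposure_knots,
                 exposure_boundary = spec$exposure_boundary,
                 exposure_df = spec$exposure_df,
                 coef = coef, vcov = (vcov + t(vcov)) / 2,
                 mmhsi = mmhsi, hsi_range = hsi_range,
                 region_id = region_id),
            class = "er_curve")
}

# Exposure basis of a reduced curve at values x.
curve_basis <- function(curve, x) {
  spec <- list(exposure_knots = curve$exposure_knots,
               exposure_boundary = curve$exposure_boundary,
               exposure_df = curve$exposure_df)
  unclass(exposure_basis(x, spec))
}

#' Locate the minimum-mortality HSI of a cumulative curve
#'
#' Argmin of the cumulative log relative risk over a 0.1 degC grid within
#' the search window; ties resolve to the lowest HSI. A flat curve (log-RR
#' range below 1e-10) triggers a warning and returns the window midpoint.
#'
#' @param curve An `er_curve`.
#' @param window Length-2 numeric search window, degC.
#' @return MMHSI in degC.
#' @export
find_mmhsi <- function(curve, window = curve$hsi_range) {
  stopifnot(inherits(curve, "er_curve"), length(window) == 2)
  grid <- seq(window[1], window[2], by = 0.1)
  logrr <- drop(curve_basis(curve, grid) %*% curve$coef)
  if (diff(range(logrr)) < 1e-10) {
    warning("flat exposure-response curve; returning window midpoint",
            call. = FALSE)
    return(mean(window))
  }
  grid[which.min(logrr)]  # first minimum = lowest HSI on ties
}

#' Relative risk at given HSI values, with 95% confidence interval
#'
#' `RR(x) = exp((B(x) - B(mmhsi)) . coef)`; the interval comes from the
#' delta method on the reduced-coefficient covariance. The curve is centred
#' at its MMHSI, so `rr_at(curve, curve$mmhsi)` is exactly 1 with a
#' degenerate interval. Values beyond the curve's observed HSI range are
#' evaluated by the natural spline's linear extrapolation; a warning is
#' issued unless `extrapolate = TRUE` (the projection path, where future
#' climates exceed the historical range by design).
#'
#' @param curve An `er_curve` with `mmhsi` set.
#' @param hsi Numeric vector of HSI values, degC.
#' @param extrapolate Suppress the out-of-range warning.
#' @return Data frame with `hsi`, `rr`, `lo`, `hi`.
#' @export
rr_at <- function(curve, hsi, extrapolate = FALSE) {
  stopifnot(inherits(curve, "er_curve"), is.finite(curve$mmhsi))
  if (!extrapolate && any(hsi < curve$hsi_range[1] | hsi > curve$hsi_range[2],
                          na.rm = TRUE))
    warning("HSI outside the curve's observed range; ",
            "log-linear extrapolation applied", call. = FALSE)
  d <- curve_basis(curve, hsi) -
    matrix(curve_basis(curve, curve$mmhsi), length(hsi),
           curve$exposure_df, byrow = TRUE)
  eta <- drop(d %*% curve$coef)
  se <- sqrt(pmax(0, rowSums((d %*% curve$vcov) * d)))
  z <- stats::qnorm(0.975)
  data.frame(hsi = hsi, rr = exp(eta),
             lo = exp(eta - z * se), hi = exp(eta + z * se))
}

#' Read daily site mortality from CSV
#'
#' Expects columns `date` (ISO-8601), `site_id`, `deaths`, and optionally
#' `region_id`.
#'
#' @param path CSV file path.
#' @return A list of `site_mortality` data frames, one per site.
#' @export
read_mortality <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "site_id", "deaths")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("mortality CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df$date <- as.Date(df$date)
  lapply(split(df, df$site_id), function(d) {
    d <- d[order(d$date), ]
    structure(data.frame(date = d$date, site_id = d$site_id[1],
                         deaths = as.integer(d$deaths)),
              region_id = if ("region_id" %in% names(d)) d$region_id[1]
                          else NA_character_,
              class = c("site_mortality", "data.frame"))
  })
}

#' Write daily site mortality to CSV
#'
#' @param sites A `site_mortality` data frame or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mortality <- function(sites, path) {
  if (is.data.frame(sites)) sites <- list(sites)
  rows <- do.call(rbind, lapply(sites, function(s) {
    data.frame(date = format(s$date, "%Y-%m-%d"), site_id = s$site_id,
               deaths = s$deaths,
               region_id = attr(s, "region_id") %||% NA_character_)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
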