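# Uncertainty propagation: Monte Carlo sampling of exposure-response
# coefficients from their multivariate normal estimate, and empirical
# ensemble envelopes across climate models and draws.

#' Sample exposure-response coefficients by Monte Carlo
#'
#' Draws from `MVN(coef, vcov)` of a reduced curve, for propagating
#' exposure-response uncertainty into attribution. A covariance that is not
#' positive semi-definite is projected to the nearest PSD matrix
#' (eigenvalue clipping) with a warning. Reproducible given the seed.
#'
#' @param curve An `er_curve`.
#' @param n Number of draws (default 1000).
#' @param seed Integer seed.
#' @return `n x exposure_df` matrix of coefficient draws.
#' @export
sample_coefficients <- function(curve, n = 1000, seed = 1L) {
  stopifnot(inherits(curve, "er_curve"), n >= 1)
  V <- (curve$vcov + t(curve$vcov)) / 2
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1e-300)) {
    warning("covariance not positive semi-definite; ",
            "nearest-PSD projection applied", call. = FALSE)
  }
  lam <- pmax(e$values, 0)
  R <- e$vectors %*% diag(sqrt(lam), length(lam))
  p <- length(curve$coef)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n * p), n, p)
    sweep(Z %*% t(R), 2, curve$coef, `+`)
  })
}

# A curve with its coefficients replaced by one Monte Carlo draw. The stored
# MMHSI is kept (no re-centring per draw).
curve_with_coef <- function(curve, coef) {
  curve$coef <- as.numeric(coef)
  curve
}

#' Empirical ensemble envelope across models and draws
#'
#' The central estimate is the arithmetic mean over models of per-model
#' means; the 95% interval spans the 2.5th to 97.5th percentiles of the
#' flattened draw-by-model distribution, with linear interpolation between
#' closest order statistics (R quantile type 7).
#'
#' @param values A list of numeric vectors (one per model, draws within),
#'   a matrix (models in rows), or a plain numeric vector (one model).
#' @return An `envelope` list: `mean`, `lo`, `hi`, `n_models`, `n_draws`.
#' @examples
#' ensemble_envelope(list(1:500, 501:1000))
#' @export
ensemble_envelope <- function(values) {
  if (is.matrix(values)) values <- split(values, row(values))
  if (is.numeric(values)) values <- list(values)
  stopifnot(is.list(values), length(values) >= 1)
  flat <- unlist(values, use.names = FALSE)
  if (length(flat) < 2)
    stop("an envelope requires at least 2 values", call. = FALSE)
  if (length(flat) < 40)
    warning("fewer than 40 values; 2.5/97.5 percentiles poorly resolved",
            call. = FALSE)
  qs <- stats::quantile(flat, c(0.025, 0.975), type = 7, names = FALSE)
  structure(list(mean = mean(vapply(values, mean, 0)),
                 lo = qs[1], hi = qs[2],
                 n_models = length(values), n_draws = length(flat)),
            class = "envelope")
}

#' Attributable deaths with Monte Carlo + ensemble uncertainty
#'
#' For each climate model's annual HSI series, draws coefficient samples
#' from the curve (per-model RNG substreams spawned from one master seed,
#' so results do not depend on evaluation order) and recomputes annual
#' attributable deaths per draw; returns the ensemble envelope together
#' with the point estimate from the mean coefficients.
#'
#' @param hsi_by_model List (one element per model) of daily HSI vectors
#'   for the same cell-year.
#' @param curve The region's `er_curve`.
#' @param mt,pop Baseline daily death rate per person; persons in the cell.
#' @param n_draws Draws per model (default 1000).
#' @param seed Master integer seed.
#' @return List with `estimate` (ensemble mean of point estimates) and
#'   `envelope` (an [ensemble_envelope()] over all draws).
#' @export
mc_attributable_deaths <- function(hsi_by_model, curve, mt, pop,
                                   n_draws = 1000, seed = 1L) {
  stopifnot(is.list(hsi_by_model), length(hsi_by_model) >= 1)
  per_model <- lapply(seq_along(hsi_by_model), function(m) {
    hsi <- hsi_by_model[[m]]
    draws <- sample_coefficients(curve, n_draws,
                                 seed = seed + 104729L * m)
    vapply(seq_len(n_draws), function(d) {
      annual_heat_deaths(hsi, curve_with_coef(curve, draws[d, ]),
                         mt, pop)$hd
    }, 0)
  })
  point <- mean(vapply(hsi_by_model, function(hsi)
    annual_heat_deaths(hsi, curve, mt, pop)$hd, 0))
  list(estimate = point, envelope = ensemble_envelope(per_model))
}
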