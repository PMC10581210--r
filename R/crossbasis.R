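# Cross-basis construction for distributed lag nonlinear models: the tensor
# product of a natural cubic spline basis over the exposure (HSI) axis and a
# natural cubic spline basis (with intercept) over lags 0..lag_max.
# Column ordering: (j, k) -> (j - 1) * lag_df + k, exposure index j slowest.

#' Specify the cross-basis of a distributed lag nonlinear model
#'
#' The exposure axis uses a natural cubic spline without intercept
#' (`df = exposure_df`); the lag axis a natural cubic spline with intercept
#' over lags `0..lag_max`. Unless given, exposure knots are placed at the
#' 10th/75th/90th percentiles of the observed HSI (standard practice for
#' temperature-mortality work) when `exposure_df = 4`, or at equally spaced
#' percentiles otherwise; lag knots are equally spaced on the log-lag scale.
#'
#' @param exposure_df Dimension of the exposure basis (`>= 2`).
#' @param exposure_knots Internal knots, degC; `NULL` to place from
#'   percentiles of the data at build time.
#' @param exposure_boundary Length-2 boundary knots, degC, or `NULL`.
#' @param lag_max Maximum lag in days (default 21).
#' @param lag_df Dimension of the lag basis (`>= 2`).
#' @param lag_knots Internal lag knots or `NULL` for log-spaced defaults.
#' @return A `crossbasis_spec` list.
#' @export
crossbasis_spec <- function(exposure_df = 4, exposure_knots = NULL,
                            exposure_boundary = NULL,
                            lag_max = 21, lag_df = 4, lag_knots = NULL) {
  # df = 1 selects the degenerate linear (exposure) / constant (lag) bases
  # used by reduction oracles; splines require df >= 2.
  stopifnot(exposure_df >= 1, lag_df >= 1, lag_max >= 1)
  if (is.null(lag_knots)) {
    nk <- max(0, lag_df - 2)  # ns with intercept: df = internal + 2
    lag_knots <- if (nk > 0)
      exp(seq(log(1), log(lag_max), length.out = nk + 2))[seq(2, nk + 1)]
    else numeric(0)
  }
  structure(list(exposure_df = exposure_df, exposure_knots = exposure_knots,
                 exposure_boundary = exposure_boundary,
                 lag_max = lag_max, lag_df = lag_df, lag_knots = lag_knots),
            class = "crossbasis_spec")
}

# Resolve data-dependent exposure knots/boundary against an observed series.
resolve_spec <- function(spec, hsi) {
  if (is.null(spec$exposure_knots)) {
    probs <- if (spec$exposure_df == 4) c(0.10, 0.75, 0.90)
             else seq_len(spec$exposure_df - 1) / spec$exposure_df
    spec$exposure_knots <- unname(
      stats::quantile(hsi, probs, na.rm = TRUE, type = 7))
  }
  if (is.null(spec$exposure_boundary))
    spec$exposure_boundary <- range(hsi, na.rm = TRUE)
  spec
}

# Exposure basis matrix at values x (no intercept).
exposure_basis <- function(x, spec) {
  stopifnot(!is.null(spec$exposure_knots), !is.null(spec$exposure_boundary))
  if (spec$exposure_df == 1) {
    matrix(x, ncol = 1)  # linear exposure basis
  } else if (length(spec$exposure_knots) == spec$exposure_df - 1) {
    splines::ns(x, knots = spec$exposure_knots,
                Boundary.knots = spec$exposure_boundary)
  } else {
    stop("exposure_knots inconsistent with exposure_df", call. = FALSE)
  }
}

# Lag basis matrix over lags 0..lag_max (with intercept), lag_max+1 x lag_df.
lag_basis <- function(spec) {
  if (spec$lag_df == 1)
    return(matrix(1, spec$lag_max + 1, 1))  # constant lag basis
  if (length(spec$lag_knots) == 0)
    splines::ns(0:spec$lag_max, df = spec$lag_df,
                Boundary.knots = c(0, spec$lag_max), intercept = TRUE)
  else
    splines::ns(0:spec$lag_max, knots = spec$lag_knots,
                Boundary.knots = c(0, spec$lag_max), intercept = TRUE)
}

#' Build the cross-basis design matrix for a daily HSI series
#'
#' Row `i`, column `(j, k)` holds
#' `sum_l B_j(HSI[i - l]) * L_k(l)` over lags `l = 0..lag_max`, where `B`
#' is the exposure basis and `L` the lag basis. The first `lag_max` rows
#' have incomplete lag history and are returned as `NA` (they are dropped
#' from the likelihood by [fit_site_model()], not imputed).
#'
#' @param hsi Daily HSI vector, degC; longer than `lag_max`.
#' @param spec A [crossbasis_spec()]; data-dependent knots are resolved
#'   against `hsi` and stored on the result.
#' @return Matrix `length(hsi) x (exposure_df * lag_df)` with attributes
#'   `spec` (resolved) and `lag_basis`.
#' @export
build_crossbasis <- function(hsi, spec = crossbasis_spec()) {
  stopifnot(inherits(spec, "crossbasis_spec"))
  n <- length(hsi)
  if (n <= spec$lag_max)
    stop("series must be longer than lag_max (", spec$lag_max, " days)",
         call. = FALSE)
  spec <- resolve_spec(spec, hsi)
  B <- exposure_basis(hsi, spec)                 # n x edf
  L <- lag_basis(spec)                           # (lag_max+1) x ldf
  edf <- ncol(B); ldf <- ncol(L)
  W <- matrix(0, n, edf * ldf)
  for (l in 0:spec$lag_max) {
    idx <- seq_len(n - l)
    Bl <- matrix(0, n, edf)
    Bl[idx + l, ] <- B[idx, , drop = FALSE]
    W <- W + kronecker(Bl, L[l + 1, , drop = FALSE])
  }
  W[seq_len(spec$lag_max), ] <- NA_real_
  colnames(W) <- paste0("cb", rep(seq_len(edf), each = ldf), ".",
                        rep(seq_len(ldf), edf))
  attr(W, "spec") <- spec
  attr(W, "lag_basis") <- L
  class(W) <- c("crossbasis", "matrix", "array")
  W
}

# Reduction matrix from cross-basis coefficients to overall-cumulative
# exposure coefficients: summing lag contributions over lags 0..lag_max.
reduction_matrix <- function(spec) {
  L <- lag_basis(spec)
  cs <- colSums(L)
  kronecker(diag(spec$exposure_df), matrix(cs, nrow = 1))
}
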