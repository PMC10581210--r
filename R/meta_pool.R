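# Second-stage pooling: multivariate random-effects meta-analysis of
# site-reduced curve coefficients per subregion. The between-site covariance
# psi is estimated by restricted maximum likelihood (REML), parameterised
# through its Cholesky factor to stay positive semi-definite, with a
# method-of-moments fallback. BLUP shrinks each site toward the pooled mean;
# the regional curve is the pooled mean re-centred at its own MMHSI.

#' Pool site exposure-response curves within a region
#'
#' Fits the multivariate random-effects model `y_s ~ N(mu, V_s + psi)` to
#' the reduced coefficient vectors of two or more sites sharing one basis,
#' estimating `psi` by REML (Cholesky-parameterised, Nelder-Mead) and
#' falling back to a method-of-moments estimate if the optimiser fails.
#' Cochran's Q, its df, p-value, and the I-squared heterogeneity statistic
#' are computed at the fixed-effect solution.
#'
#' @param curves List of `er_curve` objects from [reduce_overall()] (or of
#'   `site_fit`s, reduced internally), all with identical exposure bases.
#' @param region_id Label for the pooled region; defaults to the first
#'   curve's region.
#' @return A `region_pool`: `mu`, `vcov_mu`, `psi`, `q_stat`, `q_df`,
#'   `q_p`, `i2` (percent), `n_sites`, `method` (`"reml"` or `"mm"`),
#'   `converged`, the shared basis definition, and the site inputs.
#' @export
pool <- function(curves, region_id = NULL) {
  curves <- lapply(curves, function(x) {
    if (inherits(x, "site_fit")) reduce_overall(x) else x
  })
  stopifnot(all(vapply(curves, inherits, TRUE, "er_curve")))
  if (length(curves) < 2)
    stop("pooling requires at least 2 site curves", call. = FALSE)
  k0 <- curves[[1]]$exposure_knots; b0 <- curves[[1]]$exposure_boundary
  same <- vapply(curves, function(cv)
    isTRUE(all.equal(cv$exposure_knots, k0)) &&
      isTRUE(all.equal(cv$exposure_boundary, b0)), TRUE)
  if (!all(same))
    stop("site curves do not share an identical exposure basis; ",
         "fix knots in the crossbasis_spec before fitting", call. = FALSE)
  y <- lapply(curves, `[[`, "coef")
  V <- lapply(curves, `[[`, "vcov")
  for (Vi in V) {
    ev <- eigen(Vi, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("a site covariance matrix is not positive semi-definite",
           call. = FALSE)
  }
  p <- length(y[[1]])
  est <- reml_estimate(y, V)
  fe <- fixed_effect(y, V)
  Q <- sum(vapply(seq_along(y), function(s) {
    r <- y[[s]] - fe$mu
    drop(crossprod(r, solve(V[[s]], r)))
  }, 0))
  q_df <- (length(y) - 1) * p
  i2 <- max(0, (Q - q_df) / Q) * 100
  structure(list(
    region_id = region_id %||% curves[[1]]$region_id,
    mu = est$mu, vcov_mu = est$vcov_mu, psi = est$psi,
    q_stat = Q, q_df = q_df,
    q_p = stats::pchisq(Q, q_df, lower.tail = FALSE), i2 = i2,
    n_sites = length(y), method = est$method, converged = est$converged,
    exposure_knots = k0, exposure_boundary = b0,
    exposure_df = curves[[1]]$exposure_df,
    hsi_range = range(vapply(curves, function(cv) cv$hsi_range, c(0, 0))),
    curves = curves
  ), class = "region_pool")
}

# GLS mean and covariance at given per-site total covariances S_s.
gls_mu <- function(y, S) {
  A <- Reduce(`+`, lapply(S, solve))
  b <- Reduce(`+`, Map(function(yi, Si) solve(Si, yi), y, S))
  vcov_mu <- solve(A)
  list(mu = drop(vcov_mu %*% b), vcov_mu = (vcov_mu + t(vcov_mu)) / 2)
}

fixed_effect <- function(y, V) gls_mu(y, V)

# -2 * restricted log-likelihood (up to a constant) at psi = U'U.
reml_nll <- function(theta, y, V, p) {
  U <- matrix(0, p, p)
  U[upper.tri(U, diag = TRUE)] <- theta
  diag(U) <- exp(pmin(diag(U), 20))
  psi <- crossprod(U)
  S <- lapply(V, function(Vi) Vi + psi)
  ok <- TRUE
  ld_sum <- 0
  Ainv <- matrix(0, p, p)
  q <- 0
  A <- Reduce(`+`, lapply(S, function(Si) {
    ch <- tryCatch(chol(Si), error = function(e) NULL)
    if (is.null(ch)) { ok <<- FALSE; return(diag(p)) }
    ld_sum <<- ld_sum + 2 * sum(log(diag(ch)))
    chol2inv(ch)
  }))
  if (!ok) return(1e10)
  mu <- tryCatch(solve(A, Reduce(`+`, Map(function(yi, Si) solve(Si, yi),
                                          y, S))),
                 error = function(e) NULL)
  if (is.null(mu)) return(1e10)
  rss <- sum(vapply(seq_along(y), function(s) {
    r <- y[[s]] - mu
    drop(crossprod(r, solve(S[[s]], r)))
  }, 0))
  ldA <- determinant(A, logarithm = TRUE)$modulus
  as.numeric(ld_sum + ldA + rss)
}

# Method-of-moments starting value / fallback for psi.
psi_mm <- function(y, V) {
  Y <- do.call(rbind, y)
  Sy <- stats::cov(Y)
  Vbar <- Reduce(`+`, V) / length(V)
  psi <- Sy - Vbar
  e <- eigen((psi + t(psi)) / 2, symmetric = TRUE)
  e$vectors %*% diag(pmax(e$values, 0), length(e$values)) %*% t(e$vectors)
}

reml_estimate <- function(y, V, maxit = 2000) {
  p <- length(y[[1]])
  psi0 <- psi_mm(y, V) + diag(1e-8, p)
  U0 <- tryCatch(chol(psi0), error = function(e) diag(1e-4, p))
  theta0 <- U0
  diag(theta0) <- log(pmax(diag(U0), 1e-8))
  theta0 <- theta0[upper.tri(theta0, diag = TRUE)]
  fn <- function(th) reml_nll(th, y, V, p)
  opt <- tryCatch({
    if (length(theta0) == 1) {
      stats::optim(theta0, fn, method = "Brent", lower = -25, upper = 25)
    } else {
      o <- stats::optim(theta0, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
      if (o$convergence != 0)  # restart once from the incumbent
        o <- stats::optim(o$par, fn, method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-10))
      o
    }
  }, error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
    psi <- psi_mm(y, V)
    est <- gls_mu(y, lapply(V, function(Vi) Vi + psi))
    return(c(est, list(psi = psi, method = "mm", converged = FALSE)))
  }
  U <- matrix(0, p, p)
  U[upper.tri(U, diag = TRUE)] <- opt$par
  diag(U) <- exp(pmin(diag(U), 20))
  psi <- crossprod(U)
  est <- gls_mu(y, lapply(V, function(Vi) Vi + psi))
  c(est, list(psi = (psi + t(psi)) / 2, method = "reml",
              converged = opt$convergence == 0))
}

#' Heterogeneity statistics for a pooled region
#'
#' Cochran's Q at the fixed-effect mean, its degrees of freedom
#' `(n_sites - 1) * dim`, chi-square p-value, and
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param pool A `region_pool` from [pool()].
#' @return List with `q`, `df`, `p`, `i2`.
#' @export
heterogeneity <- function(pool) {
  stopifnot(inherits(pool, "region_pool"))
  list(q = pool$q_stat, df = pool$q_df, p = pool$q_p, i2 = pool$i2)
}

#' BLUP of a site curve given its regional pool
#'
#' Best linear unbiased prediction: the site estimate shrunk toward the
#' pooled mean with weight `psi (psi + V_s)^{-1}`,
#' `blup_s = mu + psi (psi + V_s)^{-1} (y_s - mu)`, with conditional
#' covariance `psi - psi (psi + V_s)^{-1} psi + ...` propagated from the
#' pooled-mean uncertainty. A singular `(psi + V_s)` is ridge-stabilised
#' with a warning. The returned curve is re-centred at its own MMHSI.
#'
#' @param curve The site's `er_curve`.
#' @param pool The region's `region_pool`.
#' @return An `er_curve` for the site after shrinkage.
#' @export
blup <- function(curve, pool) {
  stopifnot(inherits(curve, "er_curve"), inherits(pool, "region_pool"))
  psi <- pool$psi
  S <- psi + curve$vcov
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("singular psi + V_s; ridge-stabilised inverse used",
            call. = FALSE)
    solve(S + diag(1e-8 * mean(diag(S)) + 1e-12, nrow(S)))
  })
  K <- psi %*% Sinv
  co <- drop(pool$mu + K %*% (curve$coef - pool$mu))
  Vb <- psi - psi %*% Sinv %*% psi +
    (diag(nrow(K)) - K) %*% pool$vcov_mu %*% t(diag(nrow(K)) - K)
  spec <- list(exposure_knots = pool$exposure_knots,
               exposure_boundary = pool$exposure_boundary,
               exposure_df = pool$exposure_df)
  out <- new_er_curve(spec, co, Vb, curve$hsi_range,
                      region_id = pool$region_id)
  out$mmhsi <- find_mmhsi(out, window = curve$hsi_range)
  out
}

#' Regional exposure-response curve from a pool
#'
#' The pooled mean `mu` with its covariance, re-centred at its own MMHSI
#' within the region's observed HSI window. This is the curve attribution
#' uses for every cell of the region.
#'
#' @param pool A `region_pool`.
#' @param mmhsi_window Search window in degC; default the pooled sites'
#'   observed 1st-99th percentile span.
#' @return An `er_curve` for the region.
#' @export
region_curve <- function(pool, mmhsi_window = NULL) {
  stopifnot(inherits(pool, "region_pool"))
  if (is.null(mmhsi_window)) {
    obs <- unlist(lapply(pool$curves, function(cv) cv$hsi_range))
    mmhsi_window <- range(obs)
  }
  spec <- list(exposure_knots = pool$exposure_knots,
               exposure_boundary = pool$exposure_boundary,
               exposure_df = pool$exposure_df)
  out <- new_er_curve(spec, pool$mu, pool$vcov_mu, pool$hsi_range,
                      region_id = pool$region_id)
  out$mmhsi <- find_mmhsi(out, window = mmhsi_window)
  out
}
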