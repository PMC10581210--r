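test_that("degenerate cross-basis matches a plain GLM on moving-average exposure", {
  fx <- site_fixture(years = c(2010, 2013))
  x <- fx$hsi - mean(fx$hsi)
  site <- gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(29, 0.05), 10,
                             seed = 21)
  sp <- crossbasis_spec(exposure_df = 1, exposure_knots = numeric(0),
                        exposure_boundary = range(x), lag_df = 1)
  fit <- fit_site_model(site, x, sp)
  # oracle: quasi-Poisson GLM on the 22-day moving sum with the same
  # seasonal spline and day-of-week terms
  ms <- as.numeric(stats::filter(x, rep(1, 22), sides = 1))
  n_years <- as.numeric(diff(range(site$date))) / 365.25
  tns <- splines::ns(seq_along(ms), df = round(7 * n_years))
  dowf <- factor(format(site$date, "%u"))
  keep <- !is.na(ms) & !is.na(site$deaths)
  oracle <- stats::glm(site$deaths[keep] ~ ms[keep] + tns[keep, ] +
                         dowf[keep], family = stats::quasipoisson())
  expect_equal(unname(fit$coef), unname(stats::coef(oracle)[2]),
               tolerance = 1e-6)
})

test_that("doubling counts preserves coefficients and doubles dispersion", {
  fx <- site_fixture(years = c(2010, 2012))
  site <- gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(), 10,
                             seed = 22)
  sp <- heatmort:::resolve_spec(crossbasis_spec(), fx$hsi)
  f1 <- fit_site_model(site, fx$hsi, sp)
  site2 <- site
  site2$deaths <- 2L * site$deaths
  f2 <- fit_site_model(site2, fx$hsi, sp)
  expect_equal(f2$coef, f1$coef, tolerance = 1e-8)
  expect_equal(f2$dispersion / f1$dispersion, 2, tolerance = 0.05)
})

test_that("all-zero deaths and short records are flagged", {
  fx <- site_fixture(years = c(2010, 2012))
  site <- gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(), 10,
                             seed = 23)
  site$deaths[] <- 0L
  expect_error(fit_site_model(site, fx$hsi), "all-zero")
  fx1 <- site_fixture(years = c(2010, 2010))
  s1 <- gen_site_mortality(fx1$hsi, fx1$dates, true_risk_curve(), 10,
                           seed = 3)
  expect_warning(fit_site_model(s1, fx1$hsi), "less than 2 years")
})

test_that("find_mmhsi locates analytic minima and boundary cases", {
  # symmetric curve around 30: spline LS projection of a parabola with
  # symmetric knots is symmetric, so the argmin is exactly 30.0
  sp <- list(exposure_knots = c(26, 30, 34), exposure_boundary = c(20, 40),
             exposure_df = 4)
  grid <- seq(20, 40, 0.05)
  Bg <- heatmort:::exposure_basis(grid, sp)
  target <- (grid - 30)^2 / 100
  # fit with intercept so the projection is reflection-symmetric; the
  # constant offset does not move the argmin
  co <- stats::coef(stats::lm(target ~ Bg))[-1]
  cur <- heatmort:::new_er_curve(sp, co, diag(1e-6, 4), c(20, 40))
  expect_equal(find_mmhsi(cur, window = c(25, 35)), 30.0, tolerance = 1e-9)
  # monotone increasing curve: window lower bound
  lin <- linear_curve(slope = 0.05, hsi_range = c(0, 40))
  expect_equal(find_mmhsi(lin, window = c(10, 35)), 10)
  # flat curve: warning and window midpoint
  flat <- linear_curve(slope = 0, hsi_range = c(0, 40))
  expect_warning(mm <- find_mmhsi(flat, window = c(10, 30)), "flat")
  expect_equal(mm, 20)
})

test_that("rr_at is centred, delta-method CIs widen with distance", {
  cur <- linear_curve(mmhsi = 29, slope = 0.05, var_slope = 1e-4,
                      hsi_range = c(10, 45))
  at_ref <- rr_at(cur, 29)
  expect_identical(at_ref$rr, 1)
  expect_identical(c(at_ref$lo, at_ref$hi), c(1, 1))
  expect_equal(rr_at(cur, 34)$rr, exp(0.25), tolerance = 1e-12)
  w <- function(x) { p <- rr_at(cur, x); log(p$hi) - log(p$lo) }
  expect_true(w(35) > w(32) && w(32) > w(30))
  expect_true(w(23) > w(26))
  expect_warning(rr_at(cur, 60), "outside")
  expect_silent(rr_at(cur, 60, extrapolate = TRUE))
})

test_that("the fitted curve recovers a known smooth risk curve at one site", {
  fx <- site_fixture(years = c(2005, 2014), seed = 31)
  truth <- true_risk_curve(29, 0.05, smooth_halfwidth = 8)
  site <- gen_site_mortality(fx$hsi, fx$dates, truth, 30, seed = 32)
  sp <- heatmort:::resolve_spec(crossbasis_spec(), fx$hsi)
  cur <- reduce_overall(fit_site_model(site, fx$hsi, sp))
  expect_lt(abs(cur$mmhsi - 29), 2)
  qs <- stats::quantile(fx$hsi, c(0.01, 0.99))
  xs <- seq(qs[1], qs[2], length.out = 30)
  pred <- rr_at(cur, xs, extrapolate = TRUE)
  tr <- exp(true_log_rr(truth, xs) - true_log_rr(truth, cur$mmhsi))
  expect_gt(mean(tr >= pred$lo & tr <= pred$hi), 0.7)
})

test_that("null sites rarely exclude RR = 1 away from the minimum", {
  fx <- site_fixture(years = c(2010, 2016))
  sp <- heatmort:::resolve_spec(crossbasis_spec(), fx$hsi)
  null_truth <- true_risk_curve(29, 0, cold_slope = 0)
  excl <- vapply(1:40, function(r) {
    site <- gen_site_mortality(fx$hsi, fx$dates, null_truth, 10,
                               seed = 700 + r)
    cur <- reduce_overall(fit_site_model(site, fx$hsi, sp))
    p <- rr_at(cur, cur$mmhsi + 5, extrapolate = TRUE)
    p$lo > 1 || p$hi < 1
  }, TRUE)
  expect_lte(mean(excl), 0.15)
})

test_that("mortality CSV round-trips through write and read", {
  fx <- site_fixture(years = c(2010, 2010))
  m <- gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(), 10, seed = 2,
                          site_id = "s01", region_id = "EC")
  path <- tempfile(fileext = ".csv")
  write_mortality(m, path)
  back <- read_mortality(path)
  expect_named(back, "s01")
  expect_equal(back$s01$deaths, m$deaths)
  expect_equal(back$s01$date, m$date)
  expect_identical(attr(back$s01, "region_id"), "EC")
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_mortality(bad), "date, site_id, deaths")
})
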