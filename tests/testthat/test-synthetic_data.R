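test_that("generators are pure functions of parameters and seed", {
  g <- grid_def(c(24, 24.5), c(110, 110.5), 0.25)
  sc <- scenario_spec("x", 0.3)
  a <- gen_climate(g, sc, c(2000, 2001), seed = 9)
  b <- gen_climate(g, sc, c(2000, 2001), seed = 9)
  expect_identical(a, b)
  p1 <- gen_population(g, 1e6, 0.1, c(2000, 2020), seed = 3)
  p2 <- gen_population(g, 1e6, 0.1, c(2000, 2020), seed = 3)
  expect_identical(p1, p2)
  fx <- site_fixture(years = c(2010, 2011))
  m1 <- gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(), 10, seed = 4)
  m2 <- gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(), 10, seed = 4)
  expect_identical(m1, m2)
})

test_that("generated temperature trend matches the scenario in expectation", {
  g <- grid_def(c(24, 24.25), c(110, 110.25), 0.25)
  sc <- scenario_spec("warm", warming_rate = 0.5, noise_sd = 1)
  cg <- gen_climate(g, sc, c(2000, 2049), seed = 3)
  yr <- as.integer(format(cg$dates, "%Y"))
  annual <- tapply(cg$t[, 1, 1], yr, mean)
  f <- stats::lm(annual ~ as.numeric(names(annual)))
  slope <- stats::coef(f)[2]
  se <- summary(f)$coefficients[2, 2]
  expect_lt(abs(slope - 0.05), 3 * se)
})

test_that("humidity stays in [0, 100] and a zero trend stays within 3%", {
  g <- grid_def(c(24, 24.25), c(110, 110.25), 0.25)
  sc <- scenario_spec("wet", 0.2, rh_trend = 0, rh_mean = 95)
  cg <- gen_climate(g, sc, c(2000, 2019), seed = 8, rh_noise_sd = 15)
  expect_true(all(cg$rh >= 0 & cg$rh <= 100))
  yr <- as.integer(format(cg$dates, "%Y"))
  first <- mean(cg$rh[yr < 2010, 1, 1])
  last <- mean(cg$rh[yr >= 2010, 1, 1])
  expect_lt(abs(last - first), 3)
})

test_that("population snapshots follow geometric growth and conserve totals", {
  g <- grid_def(c(24, 25), c(110, 111), 0.25)
  flat <- gen_population(g, 1e6, 0, c(2000, 2030), seed = 2)
  for (p in flat) expect_equal(p$pop, flat[[1]]$pop)
  grow <- gen_population(g, 1e6, 0.1, c(2000, 2019), seed = 2)
  totals <- vapply(grow, function(p) sum(p$pop), 0)
  expect_equal(unname(totals[1]), 1e6, tolerance = 1e-3)
  expect_equal(unname(totals[2]), 1.1e6, tolerance = 1e-3)
  expect_true(all(vapply(grow, function(p) all(p$pop >= 0), TRUE)))
  expect_error(gen_population(g, 1e6, -1.2, c(2000, 2010)), "-100%")
})

test_that("null-risk mortality has mean at the baseline rate", {
  fx <- site_fixture(years = c(2010, 2014))
  null_truth <- true_risk_curve(29, 0, cold_slope = 0)
  m <- gen_site_mortality(fx$hsi, fx$dates, null_truth, 10, seed = 6)
  counts <- m$deaths[!is.na(m$deaths)]
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10), 3 * se)
  expect_true(all(counts >= 0 & counts == round(counts)))
})

test_that("hot days carry excess mortality under a positive heat slope", {
  fx <- site_fixture(years = c(2005, 2014))
  m <- gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(29, 0.05), 10,
                          seed = 12)
  ok <- !is.na(m$deaths)
  hsi <- fx$hsi[ok]; deaths <- m$deaths[ok]
  qs <- stats::quantile(hsi, c(0.1, 0.9))
  rate_hot <- mean(deaths[hsi >= qs[2]])
  rate_cool <- mean(deaths[hsi > qs[1] & hsi < stats::median(hsi)])
  expect_gt(rate_hot / rate_cool, 1)
})

test_that("dispersion controls the variance/mean ratio of counts", {
  fx <- site_fixture(years = c(2005, 2014))
  null_truth <- true_risk_curve(29, 0, cold_slope = 0)
  m1 <- gen_site_mortality(fx$hsi, fx$dates, null_truth, 20, dispersion = 1,
                           seed = 3)
  c1 <- m1$deaths[!is.na(m1$deaths)]
  expect_equal(stats::var(c1) / mean(c1), 1, tolerance = 0.12)
  m2 <- gen_site_mortality(fx$hsi, fx$dates, null_truth, 20, dispersion = 2,
                           seed = 3)
  c2 <- m2$deaths[!is.na(m2$deaths)]
  expect_equal(stats::var(c2) / mean(c2), 2, tolerance = 0.25)
})

test_that("day-of-week multipliers scale expected counts", {
  fx <- site_fixture(years = c(2005, 2014))
  null_truth <- true_risk_curve(29, 0, cold_slope = 0)
  dow <- c(2, 1, 1, 1, 1, 1, 1)  # Mondays doubled
  m <- gen_site_mortality(fx$hsi, fx$dates, null_truth, 20,
                          dow_effects = dow, seed = 5)
  ok <- !is.na(m$deaths)
  is_mon <- format(m$date, "%u") == "1"
  expect_equal(mean(m$deaths[ok & is_mon]) / mean(m$deaths[ok & !is_mon]),
               2, tolerance = 0.1)
})

test_that("degenerate inputs are rejected", {
  expect_error(grid_def(c(20, 21), c(110, 111), 0.3), "divide")
  expect_error(scenario_spec("x", 0.2, rh_mean = 101))
  expect_error(true_risk_curve(lag_weights = rep(1, 22)))
  fx <- site_fixture(years = c(2010, 2010))
  expect_error(gen_site_mortality(fx$hsi[1:10], fx$dates[1:10],
                                  true_risk_curve(), 10), "22 days")
  expect_error(gen_site_mortality(fx$hsi, fx$dates, true_risk_curve(), -1),
               "baseline_rate")
})

test_that("the calendar is real: leap days are generated", {
  g <- grid_def(c(24, 24.25), c(110, 110.25), 0.25)
  cg <- gen_climate(g, scenario_spec("x", 0), c(2000, 2000), seed = 1)
  expect_true(as.Date("2000-02-29") %in% cg$dates)
  expect_length(cg$dates, 366)
})
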