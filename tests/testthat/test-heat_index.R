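test_that("simple-branch values match direct arithmetic", {
  # (1.98*26 + 24.9 + 0.047*50 - 32) / 1.8
  expect_equal(heat_index(26, 50), (1.98 * 26 + 24.9 + 0.047 * 50 - 32) / 1.8,
               tolerance = 1e-12)
  expect_equal(heat_index(0, 50), (24.9 + 0.047 * 50 - 32) / 1.8,
               tolerance = 1e-12)
  expect_identical(heat_index_point(26, 50)$branch, "simple")
})

test_that("Rothfusz branch matches term-by-term polynomial evaluation", {
  tf <- 1.8 * 35.56 + 32
  rh <- 50
  hi_f <- 2.04901523 * tf - 42.379 + 10.14333127 * rh - 0.22475541 * tf * rh -
    0.00683783 * tf^2 - 0.05481717 * rh^2 + 0.00122874 * rh * tf^2 +
    0.00085282 * tf * rh^2 - 0.00000199 * tf^2 * rh^2
  expect_equal(heat_index(35.56, 50), (hi_f - 32) / 1.8, tolerance = 1e-12)
  expect_equal(heat_index(35.56, 50), 42.0, tolerance = 0.05)
  expect_identical(heat_index_point(35.56, 50)$branch, "rothfusz")
})

test_that("dry adjustment subtracts the square-root term in its window", {
  t <- 38; rh <- 10
  base <- heat_index(t, 13.5) # outside window, plain rothfusz for reference
  adj <- ((13 - rh) / 4) * sqrt(1 - abs(9 * t - 315) / 85)
  tf <- 1.8 * t + 32
  hi_f <- 2.04901523 * tf - 42.379 + 10.14333127 * rh - 0.22475541 * tf * rh -
    0.00683783 * tf^2 - 0.05481717 * rh^2 + 0.00122874 * rh * tf^2 +
    0.00085282 * tf * rh^2 - 0.00000199 * tf^2 * rh^2
  expect_equal(heat_index(t, rh), (hi_f - adj - 32) / 1.8, tolerance = 1e-12)
  expect_identical(heat_index_point(t, rh)$branch, "rothfusz_dry_adj")
  expect_identical(heat_index_point(28, 90)$branch, "rothfusz_humid_adj")
})

test_that("adjustment branches stay inside their stated windows", {
  grid <- expand.grid(t = seq(20, 50, 0.5), rh = seq(0, 100, 2.5))
  br <- vapply(seq_len(nrow(grid)), function(i)
    heat_index_point(grid$t[i], grid$rh[i])$branch, "")
  dry <- br == "rothfusz_dry_adj"
  hum <- br == "rothfusz_humid_adj"
  expect_true(all(grid$rh[dry] < 13 & grid$t[dry] >= 26.7 &
                    grid$t[dry] <= 44.5))
  expect_true(all(grid$rh[hum] > 85 & grid$t[hum] >= 26.7 &
                    grid$t[hum] <= 30.5))
  expect_false(any(dry & hum))
})

test_that("hsi is nondecreasing in temperature at fixed humidity", {
  for (rh in seq(40, 100, 15)) {
    ts <- seq(20, 44, 0.1)
    h <- heat_index(ts, rep(rh, length(ts)))
    expect_true(all(diff(h) >= -1e-12), label = paste("rh =", rh))
  }
})

test_that("blend discontinuity at the 80 degF crossover is bounded", {
  for (rh in seq(20, 80, 10)) {
    t_cross <- (80 - 24.9 - 0.047 * rh) / 1.98  # simple formula hits 80 degF
    below <- heat_index(t_cross - 1e-6, rh)
    above <- heat_index(t_cross + 1e-6, rh)
    expect_lt(abs(above - below), 1.5)
  }
})

test_that("nws mode matches the independent reference on a dense grid", {
  ts <- seq(-10, 49.8, length.out = 200)
  rhs <- seq(0, 100, length.out = 100)
  grid <- expand.grid(t = ts, rh = rhs)
  got <- heat_index(grid$t, grid$rh)
  ref <- mapply(nws_reference, grid$t, grid$rh)
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("celsius mode evaluates the printed equations verbatim", {
  # Rothfusz polynomial with t in degC, no conversion
  t <- 30; rh <- 50
  hi <- 2.04901523 * t - 42.379 + 10.14333127 * rh - 0.22475541 * t * rh -
    0.00683783 * t^2 - 0.05481717 * rh^2 + 0.00122874 * rh * t^2 +
    0.00085282 * t * rh^2 - 0.00000199 * t^2 * rh^2
  expect_equal(heat_index(t, rh, mode = "celsius"), hi, tolerance = 1e-12)
  # a Rothfusz value below 26.7 falls back to the simple formula
  t2 <- 20; rh2 <- 3
  expect_lt(2.04901523 * t2 - 42.379 + 10.14333127 * rh2 -
              0.22475541 * t2 * rh2 - 0.00683783 * t2^2 -
              0.05481717 * rh2^2 + 0.00122874 * rh2 * t2^2 +
              0.00085282 * t2 * rh2^2 - 0.00000199 * t2^2 * rh2^2, 26.7)
  expect_equal(heat_index(t2, rh2, mode = "celsius"),
               1.98 * t2 + 24.9 + 0.047 * rh2, tolerance = 1e-12)
})

test_that("inputs are validated and missing values propagate", {
  expect_error(heat_index(25, 120), "relative humidity")
  expect_error(heat_index(25, -1), "relative humidity")
  expect_error(heat_index(Inf, 50), "non-finite")
  expect_error(heat_index(70, 50), "physical range")
  expect_true(is.na(heat_index(NA, 50)))
  expect_true(is.na(heat_index(25, NA)))
})

test_that("series application is elementwise and shape-preserving", {
  cs <- climate_series(as.Date("2020-01-01") + 0:9,
                       t = seq(20, 38, 2), rh = rep(60, 10))
  h <- heat_index_series(cs)
  expect_length(h, 10)
  expect_equal(h, heat_index(cs$t, cs$rh))
  cs0 <- climate_series(as.Date(character(0)), numeric(0), numeric(0))
  expect_length(heat_index_series(cs0), 0)
  # grid input keeps the day x lat x lon shape
  fx <- site_fixture(years = c(2010, 2010))
  hg <- heat_index_series(fx$cg)
  expect_equal(dim(hg), dim(fx$cg$t))
})

test_that("summer-peaking series has its HSI maximum in summer at fixed RH", {
  dates <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  t <- 22 + 10 * cos(2 * pi * (doy - 196) / 365)
  cs <- climate_series(dates, t, rep(60, length(t)))
  h <- heat_index_series(cs)
  peak <- which.max(h)
  expect_true(doy[peak] >= 152 & doy[peak] <= 243)  # June-August
})
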