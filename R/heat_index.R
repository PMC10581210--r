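# Heat stress index (HSI): NWS-style heat index expressed in degrees Celsius.
#
# The index is piecewise. Below the 80 degF threshold a simple Steadman-type
# linear formula applies; above it the nine-term Rothfusz regression is used,
# with a low-humidity subtraction (RH < 13%, 26.7-44.5 degC) and a
# high-humidity addition (RH > 85%, 26.7-30.5 degC). The Rothfusz constants
# are Fahrenheit-scale, so the default "nws" mode evaluates internally in
# degF and converts the result to degC. The thresholds 26.7/30.5/44.5 degC
# are exactly 80/87/112 degF.

# Steadman simple formula. With t in degC this returns a Fahrenheit-scale
# value: 1.98 t + 24.9 + 0.047 rh == 1.1 T_F - 10.3 + 0.047 rh at T_F = 1.8 t + 32.
hsi_simple <- function(t, rh) 1.98 * t + 24.9 + 0.047 * rh

# Rothfusz regression, coefficients on the Fahrenheit scale.
hsi_rothfusz <- function(tf, rh) {
  2.04901523 * tf - 42.379 + 10.14333127 * rh -
    0.22475541 * tf * rh - 0.00683783 * tf^2 - 0.05481717 * rh^2 +
    0.00122874 * rh * tf^2 + 0.00085282 * tf * rh^2 -
    0.00000199 * tf^2 * rh^2
}

# Low-humidity adjustment (subtracted); t in degC. Equals the NWS form
# ((13-RH)/4) * sqrt((17-|T_F-95|)/17).
hsi_adj_dry <- function(t, rh) {
  ((13 - rh) / 4) * sqrt(pmax(0, 1 - abs(9 * t - 315) / 85))
}

# High-humidity adjustment (added); t in degC. Equals ((RH-85)/10)*((87-T_F)/5).
hsi_adj_humid <- function(t, rh) {
  ((rh - 85) / 10) * ((275 - 9 * t) / 25)
}

#' Heat stress index from temperature and relative humidity
#'
#' Computes the heat stress index (HSI), an equivalent temperature combining
#' air temperature and relative humidity, using the piecewise NWS heat-index
#' formulation: a Steadman-type simple formula when the index falls below
#' 80 degF, otherwise the Rothfusz regression with low-humidity
#' (RH < 13\%, 26.7--44.5 degC) and high-humidity (RH > 85\%,
#' 26.7--30.5 degC) adjustments. Input and output are in degrees Celsius.
#'
#' @param t Air temperature, degC. Vectorised; `NA` propagates.
#' @param rh Relative humidity, percent, in `[0, 100]`.
#' @param mode `"nws"` (default) evaluates the standard formulation
#'   internally on the Fahrenheit scale and converts the result to degC.
#'   `"celsius"` evaluates the same coefficient set directly on Celsius
#'   inputs with no unit conversion, for auditing transcriptions of the
#'   formulas that state all quantities in degC; its output is not a
#'   physically meaningful temperature.
#' @return Numeric vector of HSI values in degC (`"nws"`), or on the
#'   nominal Celsius-input scale (`"celsius"`).
#' @seealso [heat_index_point()] for the branch taken, [heat_index_series()]
#'   for [climate_series()] / [climate_grid()] input.
#' @examples
#' heat_index(35.56, 50)   # hot, moderate humidity: Rothfusz branch
#' heat_index(26, 50)      # below threshold: simple-formula branch
#' @export
heat_index <- function(t, rh, mode = c("nws", "celsius")) {
  mode <- match.arg(mode)
  check_t_rh(t, rh)
  if (mode == "nws") hsi_nws(t, rh) else hsi_celsius_literal(t, rh)
}

check_t_rh <- function(t, rh) {
  if (length(t) != length(rh))
    stop("`t` and `rh` must have the same length", call. = FALSE)
  bad_rh <- !is.na(rh) & (rh < 0 | rh > 100)
  if (any(bad_rh))
    stop("relative humidity outside [0, 100]: e.g. rh = ",
         format(rh[which(bad_rh)[1]]), call. = FALSE)
  bad_t <- !is.na(t) & !is.finite(t)
  if (any(bad_t)) stop("non-finite temperature input", call. = FALSE)
  bad_t2 <- !is.na(t) & (t <= -90 | t >= 60)
  if (any(bad_t2))
    stop("temperature outside physical range (-90, 60) degC", call. = FALSE)
  invisible(TRUE)
}

hsi_nws <- function(t, rh) {
  simple_f <- hsi_simple(t, rh)            # Fahrenheit scale
  tf <- 1.8 * t + 32
  hi_f <- hsi_rothfusz(tf, rh)
  dry <- !is.na(rh) & !is.na(t) & rh < 13 & t >= 26.7 & t <= 44.5
  hum <- !is.na(rh) & !is.na(t) & rh > 85 & t >= 26.7 & t <= 30.5
  hi_f[dry] <- hi_f[dry] - hsi_adj_dry(t[dry], rh[dry])
  hi_f[hum] <- hi_f[hum] + hsi_adj_humid(t[hum], rh[hum])
  use_simple <- !is.na(simple_f) & simple_f < 80
  out_f <- ifelse(use_simple, simple_f, hi_f)
  (out_f - 32) / 1.8
}

# Verbatim Celsius-input evaluation: Rothfusz polynomial on t in degC, the
# adjustments in their windows, and the simple formula whenever the Rothfusz
# value falls below 26.7. No unit conversion anywhere.
hsi_celsius_literal <- function(t, rh) {
  hi <- hsi_rothfusz(t, rh)
  dry <- !is.na(rh) & !is.na(t) & rh < 13 & t >= 26.7 & t <= 44.5
  hum <- !is.na(rh) & !is.na(t) & rh > 85 & t >= 26.7 & t <= 30.5
  hi[dry] <- hi[dry] - hsi_adj_dry(t[dry], rh[dry])
  hi[hum] <- hi[hum] + hsi_adj_humid(t[hum], rh[hum])
  use_simple <- !is.na(hi) & hi < 26.7
  ifelse(use_simple, hsi_simple(t, rh), hi)
}

#' Heat stress index at a single point, with the branch taken
#'
#' As [heat_index()] but scalar, returning both the value and which branch
#' of the piecewise definition produced it.
#'
#' @inheritParams heat_index
#' @return A list with `hsi` (degC) and `branch`, one of `"simple"`,
#'   `"rothfusz"`, `"rothfusz_dry_adj"`, `"rothfusz_humid_adj"`.
#' @examples
#' heat_index_point(38, 10)$branch   # "rothfusz_dry_adj"
#' @export
heat_index_point <- function(t, rh, mode = c("nws", "celsius")) {
  mode <- match.arg(mode)
  stopifnot(length(t) == 1, length(rh) == 1)
  hsi <- heat_index(t, rh, mode)
  if (is.na(hsi)) return(list(hsi = NA_real_, branch = NA_character_))
  simple_branch <- if (mode == "nws") hsi_simple(t, rh) < 80
                   else hsi_rothfusz(t, rh) < 26.7
  branch <-
    if (simple_branch) "simple"
    else if (rh < 13 && t >= 26.7 && t <= 44.5) "rothfusz_dry_adj"
    else if (rh > 85 && t >= 26.7 && t <= 30.5) "rothfusz_humid_adj"
    else "rothfusz"
  list(hsi = hsi, branch = branch)
}

#' Heat stress index for a daily climate series or grid
#'
#' Applies [heat_index()] elementwise to a [climate_series()] (returning a
#' numeric vector, one value per day) or a [climate_grid()] (returning an
#' array with the grid's `day x lat x lon` shape). Missing input days
#' propagate missing values.
#'
#' @param x A `climate_series` or `climate_grid`.
#' @inheritParams heat_index
#' @return Numeric vector (series) or array (grid) of HSI in degC.
#' @export
heat_index_series <- function(x, mode = c("nws", "celsius")) {
  mode <- match.arg(mode)
  if (inherits(x, "climate_series")) {
    heat_index(x$t, x$rh, mode)
  } else if (inherits(x, "climate_grid")) {
    out <- heat_index(as.vector(x$t), as.vector(x$rh), mode)
    array(out, dim = dim(x$t), dimnames = dimnames(x$t))
  } else {
    stop("`x` must be a climate_series or climate_grid", call. = FALSE)
  }
}
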