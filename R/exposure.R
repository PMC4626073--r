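#' Coefficients of the dew-point apparent-temperature index
#'
#' The apparent temperature used throughout the package is the
#' Kalkstein--Valimont thermal-discomfort index in its dew-point form,
#' \deqn{AT = c_0 + c_1 T + c_2 T_d^2,}
#' with air temperature \eqn{T} and dew point \eqn{T_d} in degrees Celsius.
#' The default coefficients are the ones standard in the heat-epidemiology
#' literature. They are exposed here so that an alternative variant of the
#' index can be swapped in without touching the rest of the pipeline.
#'
#' @param intercept,temp,dewpoint_sq coefficients \eqn{c_0, c_1, c_2}.
#' @return A named numeric vector of length 3.
#' @export
#' @examples
#' at_coefficients()
at_coefficients <- function(intercept = -2.653, temp = 0.994,
                            dewpoint_sq = 0.0153) {
  c(intercept = intercept, temp = temp, dewpoint_sq = dewpoint_sq)
}

#' Apparent temperature from air temperature and dew point
#'
#' Computes the daily mean apparent temperature (degrees C), a thermal-discomfort
#' index combining air temperature and humidity through the dew point.
#' Missing inputs yield a missing apparent temperature (to be imputed
#' downstream with [impute_adjacent_mean()]), not an error. Dew point larger
#' than temperature is physically odd but the record is kept as-is.
#'
#' @param temp daily mean air temperature, degrees C (vectorised).
#' @param dewpoint daily mean dew point, degrees C (vectorised).
#' @param coefs index coefficients, see [at_coefficients()].
#' @return numeric vector of apparent temperatures, degrees C.
#' @export
#' @examples
#' apparent_temperature(25, 15)   # 25.6395
#' apparent_temperature(30, 20)   # 33.287
apparent_temperature <- function(temp, dewpoint, coefs = at_coefficients()) {
  stopifnot(length(coefs) == 3L)
  at <- coefs[[1L]] + coefs[[2L]] * temp + coefs[[3L]] * dewpoint^2
  bad <- is.finite(at) & (is.infinite(temp) | is.infinite(dewpoint))
  at[bad] <- NA_real_
  at
}

#' Fill isolated missing days with the adjacent-day mean
#'
#' Replaces each missing entry of a daily series by the arithmetic mean of the
#' previous and following day's values. This is the standard patch for the
#' occasional missing weather day in warm-season surveillance series; it is
#' only defined when missing days are isolated (no two consecutive) and not at
#' a season boundary, and the function errors otherwise, naming the offending
#' day.
#'
#' @param x numeric vector, daily values with possible `NA`s.
#' @param labels labels used in error messages (e.g. dates); defaults to the
#'   positional index.
#' @return `x` with every `NA` replaced; non-missing entries are unchanged.
#' @export
#' @examples
#' impute_adjacent_mean(c(20, NA, 24))  # 20 22 24
impute_adjacent_mean <- function(x, labels = seq_along(x)) {
  stopifnot(length(labels) == length(x))
  miss <- which(is.na(x))
  if (length(miss) == 0L) return(x)
  n <- length(x)
  for (i in miss) {
    if (i == 1L || i == n)
      stop("cannot impute missing value at season boundary: ", labels[i])
    if (is.na(x[i - 1L]) || is.na(x[i + 1L]))
      stop("cannot impute consecutive missing days around: ", labels[i])
  }
  x[miss] <- (x[miss - 1L] + x[miss + 1L]) / 2
  x
}

#' Average PM10 over the reporting monitoring stations
#'
#' Daily PM10 exposure is the arithmetic mean of the daily means at the
#' available monitoring stations; when only one station reports, its value is
#' used directly. A day with no reporting station at all is an error (such
#' days must be handled upstream).
#'
#' @param station_values numeric vector of station daily means (micrograms/m3);
#'   `NA` entries count as non-reporting.
#' @return single numeric value, micrograms/m3.
#' @export
#' @examples
#' average_stations(c(20, 30))  # 25
#' average_stations(c(26.5, NA))  # 26.5, single-station fallback
average_stations <- function(station_values) {
  v <- station_values[!is.na(station_values)]
  if (length(v) == 0L)
    stop("no station reported a PM10 value for this day")
  if (any(v < 0))
    stop("negative PM10 station value")
  mean(v)
}

#' Mean of a daily series over a window of lags
#'
#' For each day t, returns the mean of `x` over days `t - l` for the lags `l`
#' in `window`. Days whose window reaches before the start of the series get
#' `NA` and are excluded from model fitting (the lag chain never crosses a
#' season boundary: apply this function per season).
#'
#' @param x complete numeric vector (one value per consecutive day).
#' @param window set of non-negative integer lags, a subset of 0..5.
#' @return numeric vector of the same length as `x`, `NA` where undefined.
#' @export
#' @examples
#' lag_window_mean(c(26, 27, 28, 29), 0:3)  # NA NA NA 27.5
lag_window_mean <- function(x, window) {
  window <- as.integer(window)
  stopifnot(length(window) >= 1L, all(window >= 0L), all(window <= 5L),
            !anyNA(x))
  n <- length(x)
  out <- rep(NA_real_, n)
  maxlag <- max(window)
  if (n <= maxlag) return(out)
  acc <- rep(0, n - maxlag)
  idx <- (maxlag + 1L):n
  for (l in window) acc <- acc + x[idx - l]
  out[idx] <- acc / length(window)
  out
}

# lagged copy of x (within one season), NA-padded at the start
shift_lag <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  c(rep(NA_real_, min(k, n)), x[seq_len(max(n - k, 0L))])
}

#' Build the per-day exposure series
#'
#' Turns raw daily weather and pollution records into the exposure series the
#' regression module consumes: apparent temperature (computed from temperature
#' and dew point unless supplied directly), adjacent-day imputation of isolated
#' missing apparent temperatures, station-averaged PM10, and the lagged
#' exposures and lag-window means (lags 1-3, windows 0-3 and 0-5). Imputation
#' happens before lagging, so lagged values never mix imputed and raw values
#' inconsistently; lags are computed within each warm season separately and
#' never cross the winter gap.
#'
#' @param weather data.frame with one row per day, columns `date` (Date) and
#'   either `apparent_temp` or both `mean_temp` and `dewpoint`; PM10 comes
#'   either as `pm10_mean` or as station columns `pm10_station1`,
#'   `pm10_station2`.
#' @param at_coefs apparent-temperature coefficients, see [at_coefficients()].
#' @return data.frame with columns `date`, `season` (calendar year),
#'   `tempapp`, `tempapp_l1`, `tempapp_l2`, `tempapp_l3`, `tempapp_l03`,
#'   `tempapp_l05`, `pm10_mean`, ordered by date.
#' @export
build_exposure_series <- function(weather, at_coefs = at_coefficients()) {
  stopifnot(is.data.frame(weather), "date" %in% names(weather))
  w <- weather[order(weather$date), , drop = FALSE]
  if (anyDuplicated(w$date)) stop("duplicated dates in weather input")

  if (!"apparent_temp" %in% names(w)) {
    if (!all(c("mean_temp", "dewpoint") %in% names(w)))
      stop("need either apparent_temp or mean_temp + dewpoint columns")
    w$apparent_temp <- apparent_temperature(w$mean_temp, w$dewpoint, at_coefs)
  }
  if (!"pm10_mean" %in% names(w)) {
    st <- intersect(c("pm10_station1", "pm10_station2"), names(w))
    if (length(st) == 0L)
      stop("need either pm10_mean or pm10_station1/pm10_station2 columns")
    w$pm10_mean <- apply(as.matrix(w[st]), 1L, average_stations)
  }

  w$season <- as.integer(format(w$date, "%Y"))
  out <- lapply(split(w, w$season), function(s) {
    if (any(diff(s$date) != 1))
      stop("days are not consecutive within season ", s$season[1L])
    at <- impute_adjacent_mean(s$apparent_temp, labels = format(s$date))
    data.frame(
      date = s$date, season = s$season,
      tempapp = at,
      tempapp_l1 = shift_lag(at, 1L),
      tempapp_l2 = shift_lag(at, 2L),
      tempapp_l3 = shift_lag(at, 3L),
      tempapp_l03 = lag_window_mean(at, 0:3),
      tempapp_l05 = lag_window_mean(at, 0:5),
      pm10_mean = s$pm10_mean
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
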