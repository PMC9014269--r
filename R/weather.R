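#' Default synthetic climate parameters
#'
#' A temperate-lowland climate in the style of eastern France: annual mean
#' temperature 11 degC with a 8 degC seasonal half-amplitude, seasonal PAR
#' between about 1.5 and 8 MJ/m2/d, and rainfall as marked Poisson events
#' (on average 0.35 events/day of mean depth 5 mm, ~640 mm/yr). The
#' generator is intentionally simple: its role is to exercise the
#' temperature-, light- and rain-dependent code paths, not climate realism.
#'
#' @return named list of climate parameters.
#' @export
default_climate <- function() {
  list(tempMean = 11, tempAmplitude = 8, tempSd = 3,
       parMid = 4.75, parAmplitude = 3.25, parSd = 0.8,
       rainRate = 0.35, rainMeanDepth = 5, startYear = 2001)
}

#' Seasonal mean-temperature sinusoid
#'
#' `T(doy) = tempMean + tempAmplitude * sin(2 pi (doy - 105) / 365.25)`,
#' peaking in early July and bottoming in early January.
#'
#' @param doy day of year (1-366).
#' @param climate climate parameter list, see [default_climate()].
#' @return mean temperature (degC).
#' @export
seasonal_temperature <- function(doy, climate = default_climate()) {
  climate$tempMean +
    climate$tempAmplitude * sin(2 * pi * (doy - 105) / 365.25)
}

#' Seasonal PAR curve
#'
#' Same phase as the temperature sinusoid:
#' `PAR(doy) = parMid + parAmplitude * sin(2 pi (doy - 80) / 365.25)`.
#'
#' @inheritParams seasonal_temperature
#' @return photosynthetically active radiation (MJ/m2/d).
#' @export
seasonal_par <- function(doy, climate = default_climate()) {
  climate$parMid + climate$parAmplitude * sin(2 * pi * (doy - 80) / 365.25)
}

#' Generate a daily weather series
#'
#' Daily mean temperature is the seasonal sinusoid plus AR(0) Gaussian noise
#' (`tempSd`); PAR is its seasonal curve plus truncated Gaussian noise;
#' rainfall is a marked Poisson process (Poisson event count per day,
#' exponential depths). Deterministic under `seed`.
#'
#' @param nYears number of calendar years (>= 1), starting 1 January of
#'   `climate$startYear`.
#' @param seed integer seed.
#' @param climate climate parameter list, see [default_climate()].
#' @return data frame with columns `date` (Date), `meanTemperature` (degC),
#'   `PAR` (MJ/m2/d), `rainfall` (mm).
#' @export
gen_weather <- function(nYears, seed = 1, climate = default_climate()) {
  stopifnot(nYears >= 1)
  start <- as.Date(sprintf("%d-01-01", climate$startYear))
  end <- as.Date(sprintf("%d-12-31", climate$startYear + nYears - 1))
  dates <- seq(start, end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  n <- length(dates)
  with_stream(seed, "weather", {
    temp <- seasonal_temperature(doy, climate) + rnorm(n, 0, climate$tempSd)
    par <- pmax(0, seasonal_par(doy, climate) + rnorm(n, 0, climate$parSd))
    events <- rpois(n, climate$rainRate)
    rain <- vapply(events, function(k)
      if (k == 0) 0 else sum(stats::rexp(k, 1 / climate$rainMeanDepth)),
      numeric(1))
    data.frame(date = dates, meanTemperature = temp, PAR = par,
               rainfall = rain)
  })
}

#' Read / write weather series CSV
#'
#' ISO-8601 dates, one row per day.
#'
#' @param weather weather data frame as from [gen_weather()].
#' @param path file path.
#' @export
write_weather_csv <- function(weather, path) {
  write.csv(weather, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_weather_csv
#' @export
read_weather_csv <- function(path) {
  w <- read.csv(path, stringsAsFactors = FALSE)
  w$date <- as.Date(w$date)
  stopifnot(all(diff(w$date) == 1), all(w$PAR >= 0), all(w$rainfall >= 0))
  w
}
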