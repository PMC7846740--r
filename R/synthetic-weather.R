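# Synthetic weather generator with Afar-like diurnal and seasonal structure.
# Every quantity is a deterministic function of the spec seed, and the rain
# model has a closed-form expectation so the annual total can be checked.

#' Climate specification for the weather generator
#'
#' Defaults describe the semi-arid Afar lowlands: ~560 mm/yr rainfall
#' concentrated in July-September, 31 degC mean temperature, ~91 kPa air
#' pressure and clear-sky solar peaks near 1000 W/m2.
#'
#' @param annual_rainfall Expected annual rainfall total, mm/yr.
#' @param mean_temp Mean annual air temperature, degC.
#' @param temp_amplitude_diurnal Peak-to-trough diurnal temperature range, degC.
#' @param mean_pressure Mean air pressure, kPa.
#' @param peak_solar Clear-sky solar maximum, W/m2.
#' @param rainy_season_months Month indices in which rain can fall.
#' @param wet_day_prob Probability a rainy-season day has rain.
#' @param rain_shape Gamma shape of daily rain amounts.
#' @param seed Integer seed; the generator is a deterministic function of it.
#' @return A `climate_spec` list.
#' @export
climate_spec <- function(annual_rainfall = 560, mean_temp = 31,
                         temp_amplitude_diurnal = 10, mean_pressure = 91,
                         peak_solar = 1000, rainy_season_months = 7:9,
                         wet_day_prob = 0.45, rain_shape = 0.8, seed = 1L) {
  check_that(annual_rainfall >= 0, "annual_rainfall must be >= 0")
  check_that(peak_solar > 0 && peak_solar <= 1400,
             "peak_solar must be in (0, 1400] W/m2")
  check_that(mean_pressure > 80 && mean_pressure < 105,
             "mean_pressure must be in (80, 105) kPa")
  check_that(wet_day_prob > 0 && wet_day_prob <= 1,
             "wet_day_prob must be in (0, 1]")
  check_that(length(rainy_season_months) >= 1 &&
               all(rainy_season_months %in% 1:12),
             "rainy_season_months must be month indices 1-12")
  structure(list(annual_rainfall = annual_rainfall, mean_temp = mean_temp,
                 temp_amplitude_diurnal = temp_amplitude_diurnal,
                 mean_pressure = mean_pressure, peak_solar = peak_solar,
                 rainy_season_months = sort(unique(rainy_season_months)),
                 wet_day_prob = wet_day_prob, rain_shape = rain_shape,
                 seed = as.integer(seed)),
            class = "climate_spec")
}

# Gamma scale such that the expected annual rain total equals the spec total:
# E[total] = (days in rainy months per year) * p_wet * shape * scale.
rain_gamma_scale <- function(spec) {
  n_days <- 365.25 / 12 * length(spec$rainy_season_months)
  if (spec$annual_rainfall == 0) return(0)
  spec$annual_rainfall / (n_days * spec$wet_day_prob * spec$rain_shape)
}

# Sampling standard deviation of a simulated annual rain total (used by the
# generator's own Monte-Carlo self-check): total over N eligible days of
# Bernoulli(p) * Gamma(shape, scale).
rain_total_sd <- function(spec, n_rainy_days) {
  sc <- rain_gamma_scale(spec)
  p <- spec$wet_day_prob
  m <- spec$rain_shape * sc
  v <- spec$rain_shape * sc^2
  sqrt(n_rainy_days * p * (v + (1 - p) * m^2))
}

#' Generate half-hourly synthetic weather
#'
#' Solar radiation is zero at night and peaks near noon; temperature follows
#' seasonal plus diurnal sinusoids; relative humidity is inversely coupled to
#' temperature; rain falls only in rainy-season months as Bernoulli wet days
#' with gamma-distributed amounts scaled so the expected annual total equals
#' `spec$annual_rainfall`.
#'
#' @param spec A [climate_spec()].
#' @param start Start date (`Date` or coercible).
#' @param days Number of days to simulate (>= 1).
#' @return Data frame of half-hourly records with interval-ending `timestamp`
#'   (UTC) and columns `solar_wm2`, `air_temp_c`, `rh_pct`, `wind_ms`,
#'   `rain_mm`, `pressure_kpa`.
#' @export
generate_weather <- function(spec, start = as.Date("2017-01-01"), days = 30) {
  stopifnot(inherits(spec, "climate_spec"))
  days <- as.integer(days)
  check_that(days >= 1, "days must be >= 1")
  start <- as.Date(start)
  with_seed(spec$seed, {
    n <- 48L * days
    t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
    timestamp <- t0 + seq_len(n) * 1800
    # mid-interval decimal hour and day-of-year drive the diurnal cycles
    mid <- timestamp - 900
    hour <- as.numeric(format(mid, "%H", tz = "UTC")) +
      as.numeric(format(mid, "%M", tz = "UTC")) / 60
    doy <- as.integer(format(mid, "%j", tz = "UTC"))
    day_idx <- rep(seq_len(days), each = 48L)
    month <- month_of(mid)

    # daily rain: Bernoulli wet days in rainy months, gamma amounts
    day_month <- month[seq(1L, n, by = 48L)]
    eligible <- day_month %in% spec$rainy_season_months
    wet <- eligible & (stats::runif(days) < spec$wet_day_prob)
    amount <- numeric(days)
    sc <- rain_gamma_scale(spec)
    if (any(wet) && sc > 0)
      amount[wet] <- stats::rgamma(sum(wet), shape = spec$rain_shape,
                                   scale = sc)
    rain <- numeric(n)
    for (d in which(amount > 0)) {
      # spread a wet day's total over 1-4 afternoon/evening half hours
      k <- sample.int(4L, 1L)
      slots <- sample(26:44, k)         # 12:30-22:00 local
      w <- stats::runif(k); w <- w / sum(w)
      rain[(d - 1L) * 48L + slots] <- amount[d] * w
    }

    # per-day cloudiness attenuates solar input (wet days are cloudier)
    cloud <- stats::runif(days, 0.8, 1.0)
    cloud[wet] <- stats::runif(sum(wet), 0.35, 0.7)
    season <- 0.92 + 0.08 * cos(2 * pi * (doy - 166) / 365)
    elev <- pmax(0, sin(pi * (hour - 6.25) / 11.5))   # daylight ~06:15-17:45
    solar <- spec$peak_solar * cloud[day_idx] * season * elev^1.2

    temp_season <- 4 * cos(2 * pi * (doy - 166) / 365)
    temp <- spec$mean_temp + temp_season +
      (spec$temp_amplitude_diurnal / 2) * cos(2 * pi * (hour - 14.5) / 24) +
      stats::rnorm(n, sd = 0.6)
    temp <- temp - 2.5 * (amount[day_idx] > 0)   # rain days run cooler

    rh <- 52 + 20 * (amount[day_idx] > 0) - 2.2 * (temp - spec$mean_temp) +
      stats::rnorm(n, sd = 3)
    rh <- pmin(100, pmax(5, rh))

    wind <- exp(stats::rnorm(n, log(1.8), 0.35)) * (1 + 0.35 * (solar > 0))
    pressure <- spec$mean_pressure +
      0.15 * cos(2 * pi * (hour - 4) / 24) + stats::rnorm(n, sd = 0.04)

    data.frame(timestamp = timestamp,
               solar_wm2 = round(solar, 2),
               air_temp_c = round(temp, 3),
               rh_pct = round(rh, 2),
               wind_ms = round(wind, 3),
               rain_mm = round(rain, 3),
               pressure_kpa = round(pressure, 3))
  })
}

#' Generate soil moisture, soil temperature and heat-flux-plate series
#'
#' Volumetric soil moisture responds to rainfall as a leaky bucket (daily
#' infiltration gain, first-order drainage), which gives the driver
#' regressions a realistic rainfall-correlated predictor. Soil temperature
#' follows a damped diurnal wave; the plate series is a daytime fraction of
#' the solar input.
#'
#' @param weather Output of [generate_weather()].
#' @param theta0 Initial volumetric soil moisture, percent.
#' @param gain Infiltration gain, percentage points of moisture per mm rain.
#' @param drain_rate First-order daily drainage rate towards `theta_dry`.
#' @param theta_dry Dry-end moisture asymptote, percent.
#' @param seed Seed for measurement noise.
#' @return Data frame with `timestamp`, `soil_moisture_pct`, `soil_temp_c`,
#'   `g_plate_wm2`.
#' @export
generate_soil_series <- function(weather, theta0 = 14, gain = 0.35,
                                 drain_rate = 0.05, theta_dry = 7,
                                 seed = 1L) {
  date <- interval_date(weather$timestamp, 1800)
  rain_daily <- tapply(weather$rain_mm, date, sum)
  nd <- length(rain_daily)
  theta <- numeric(nd)
  th <- theta0
  for (d in seq_len(nd)) {
    th <- th + gain * rain_daily[[d]] - drain_rate * (th - theta_dry)
    th <- min(45, max(3, th))
    theta[d] <- th
  }
  with_seed(seed, {
    theta_hh <- theta[match(date, names(rain_daily))] +
      stats::rnorm(nrow(weather), sd = 0.15)
    soil_t <- 0.75 * weather$air_temp_c + 0.25 * mean(weather$air_temp_c) +
      stats::rnorm(nrow(weather), sd = 0.2)
    g_plate <- 0.09 * weather$solar_wm2 - 9 +
      stats::rnorm(nrow(weather), sd = 1.5)
    data.frame(timestamp = weather$timestamp,
               soil_moisture_pct = round(pmax(1, theta_hh), 3),
               soil_temp_c = round(soil_t, 3),
               g_plate_wm2 = round(g_plate, 2))
  })
}
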