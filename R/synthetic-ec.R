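# Synthetic high-frequency eddy-covariance records with prescribed fluxes,
# and a half-hourly surface-flux series with a prescribed crop coefficient.

#' Turbulence window specification
#'
#' @param target_LE Prescribed latent heat flux, W/m2 (after density
#'   adjustment -- the generator emits the raw densities a sensor would
#'   see).
#' @param target_H Prescribed sensible heat flux, W/m2.
#' @param sampling_hz Sampling rate, Hz (10 Hz instrumentation standard).
#' @param window_minutes Averaging window length, minutes.
#' @param mean_wind Mean horizontal wind, m/s.
#' @param tilt_deg Sensor tilt `c(yaw, pitch)` in degrees; double rotation
#'   removes exactly this class of tilt.
#' @param mean_sonic_temp Mean sonic temperature, degC.
#' @param mean_h2o Mean water-vapour density, g/m3.
#' @param pressure Air pressure, kPa.
#' @param seed Integer seed.
#' @return A `turbulence_spec` list.
#' @export
turbulence_spec <- function(target_LE = 200, target_H = 100,
                            sampling_hz = 10, window_minutes = 30,
                            mean_wind = 2, tilt_deg = c(0, 0),
                            mean_sonic_temp = 30, mean_h2o = 10,
                            pressure = 91, seed = 1L) {
  check_that(sampling_hz > 0, "sampling_hz must be > 0")
  check_that(window_minutes >= 1, "window_minutes must be >= 1")
  check_that(mean_wind > 0, "mean_wind must be > 0")
  structure(list(target_LE = target_LE, target_H = target_H,
                 sampling_hz = sampling_hz,
                 window_minutes = window_minutes, mean_wind = mean_wind,
                 tilt_deg = tilt_deg, mean_sonic_temp = mean_sonic_temp,
                 mean_h2o = mean_h2o, pressure = pressure,
                 seed = as.integer(seed)),
            class = "turbulence_spec")
}

# Raw covariances implying the spec's target fluxes, by inverting the same
# flux equations ec_fluxes applies (H is linear in cov_wT; after fixing
# cov_wT, LE is affine in cov_wq).
target_covariances <- function(spec) {
  cov_wt <- spec$target_H /
    h_from_cov(1, spec$mean_sonic_temp, spec$mean_h2o, spec$pressure)
  le0 <- le_from_cov(0, cov_wt, spec$mean_sonic_temp, spec$mean_h2o,
                     spec$pressure)
  le1 <- le_from_cov(1, cov_wt, spec$mean_sonic_temp, spec$mean_h2o,
                     spec$pressure)
  cov_wq <- (spec$target_LE - le0) / (le1 - le0)
  c(cov_wt = cov_wt, cov_wq = cov_wq)
}

# Sampling standard error of a covariance estimate over n samples:
# var(cov_hat) ~ (var_x var_y + cov^2) / n.
covariance_se <- function(var_x, var_y, cov_xy, n) {
  sqrt((var_x * var_y + cov_xy^2) / n)
}

#' Generate a high-frequency eddy-covariance window
#'
#' Gaussian w'/T'/q' fluctuations are mixed through a Cholesky factor of
#' the prescribed covariance matrix and then empirically whitened, so the
#' sample second moments match the prescription exactly; the prescribed
#' raw covariances are those that yield `target_H` and `target_LE` after
#' the WPL density adjustment. An optional yaw/pitch tilt is applied so
#' that double rotation is exercised.
#'
#' @param spec A [turbulence_spec()].
#' @return Data frame `u`, `v`, `w`, `T_sonic` (degC), `h2o_gm3`, with
#'   attributes `sampling_hz`, `true_cov` and `spec`.
#' @export
generate_turbulence <- function(spec) {
  stopifnot(inherits(spec, "turbulence_spec"))
  n <- as.integer(round(spec$sampling_hz * spec$window_minutes * 60))
  tc <- target_covariances(spec)
  sd_w <- 0.4
  sd_t <- max(0.25, abs(tc["cov_wt"]) / (0.7 * sd_w))
  sd_q <- max(0.15, abs(tc["cov_wq"]) / (0.7 * sd_w))
  cov_tq <- 0.3 * sd_t * sd_q *
    if (tc["cov_wt"] * tc["cov_wq"] < 0) -1 else 1
  sigma <- matrix(c(sd_w^2, tc["cov_wt"], tc["cov_wq"],
                    tc["cov_wt"], sd_t^2, cov_tq,
                    tc["cov_wq"], cov_tq, sd_q^2), 3, 3)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {   # drop the T-q cross term if it breaks definiteness
    sigma[2, 3] <- sigma[3, 2] <- 0
    ch <- chol(sigma)
  }
  with_seed(spec$seed, {
    z <- matrix(stats::rnorm(n * 3L), n, 3L)
    z <- scale(z, center = TRUE, scale = FALSE)
    wtq <- z %*% solve(chol(stats::cov(z))) %*% ch
    up <- stats::rnorm(n, sd = 0.9); up <- up - mean(up)
    vp <- stats::rnorm(n, sd = 0.6); vp <- vp - mean(vp)
    uvw <- cbind(spec$mean_wind + up, vp, wtq[, 1])
    yaw <- spec$tilt_deg[1] * pi / 180
    pitch <- spec$tilt_deg[2] * pi / 180
    if (yaw != 0 || pitch != 0) {
      # measured = yaw' pitch' true: exactly what double rotation undoes
      uvw <- uvw %*% rot_pitch(pitch) %*% rot_yaw(yaw)
    }
    out <- data.frame(u = uvw[, 1], v = uvw[, 2], w = uvw[, 3],
                      T_sonic = spec$mean_sonic_temp + wtq[, 2],
                      h2o_gm3 = spec$mean_h2o + wtq[, 3])
    attr(out, "sampling_hz") <- spec$sampling_hz
    attr(out, "true_cov") <- tc
    attr(out, "spec") <- spec
    out
  })
}

#' Generate a half-hourly surface-flux series with known crop coefficient
#'
#' Builds interval ETo from the weather table (FAO-56 hourly form), sets
#' daily ETa to `kc_true * ETo + noise`, distributes it over the day
#' proportionally to interval ETo, and derives the energy-balance-closed
#' flux partition (`LE` from ETa, `H = Rn - G - LE`).
#'
#' @param weather Half-hourly weather table.
#' @param kc_true Prescribed crop coefficient (default 0.77).
#' @param noise_sd_daily SD of daily ETa noise, mm/day.
#' @param seed Integer seed.
#' @return List with `interval` (timestamp, rn_wm2, g_wm2, le_wm2, h_wm2,
#'   eta_mm, eto_mm) and `daily` (date, eto_mm, eta_mm).
#' @export
generate_flux_series <- function(weather, kc_true = 0.77,
                                 noise_sd_daily = 0.2, seed = 1L) {
  eto <- eto_from_weather(weather)
  dt_s <- as.numeric(stats::median(diff(as.numeric(weather$timestamp))))
  date <- interval_date(weather$timestamp, dt_s)
  daily <- eto$daily
  daily$eta_mm <- with_seed(seed, {
    pmax(0, kc_true * daily$eto_mm +
           stats::rnorm(nrow(daily), sd = noise_sd_daily))
  })
  # distribute daily ETa over intervals proportionally to interval ETo
  day_tot <- daily$eto_mm[match(date, daily$date)]
  day_eta <- daily$eta_mm[match(date, daily$date)]
  share <- ifelse(day_tot > 0, eto$interval$eto_mm / day_tot, 0)
  eta_int <- day_eta * share
  lambda_jkg <- latent_heat(weather$air_temp_c) * 1e6
  le <- eta_int * lambda_jkg / dt_s
  rn <- net_radiation_estimate(weather$solar_wm2)
  g <- ground_flux_estimate(rn, weather$solar_wm2 > 10)
  interval <- data.frame(timestamp = weather$timestamp,
                         rn_wm2 = rn, g_wm2 = g, le_wm2 = le,
                         h_wm2 = rn - g - le, eta_mm = eta_int,
                         eto_mm = eto$interval$eto_mm)
  list(interval = interval, daily = daily)
}
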