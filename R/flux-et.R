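# Eddy-covariance flux processing (despiking, double rotation, lag
# correction, WPL density adjustment), soil heat flux with storage
# correction, FAO-56 Penman-Monteith reference ET, and the crop coefficient.

#' Despike a high-frequency window
#'
#' Points farther than `mad_threshold` robust SDs (scaled MAD) from the
#' window median are replaced by linear interpolation. Windows with more
#' than 10% of points replaced in any column are flagged low quality.
#'
#' @param window Data frame of high-frequency records.
#' @param cols Columns to despike.
#' @param mad_threshold Threshold in MAD units (default 6).
#' @return The window with attributes `n_replaced` (named per column) and
#'   `qc_low_quality`.
#' @export
despike <- function(window, cols = c("u", "v", "w", "T_sonic", "h2o_gm3"),
                    mad_threshold = 6) {
  check_that(nrow(window) > 0, "window is empty")
  cols <- intersect(cols, names(window))
  n_rep <- integer(0)
  for (cl in cols) {
    x <- window[[cl]]
    med <- stats::median(x, na.rm = TRUE)
    s <- stats::mad(x, na.rm = TRUE)
    # with zero MAD (constant series) only non-finite points are spikes
    bad <- !is.finite(x)
    if (s > 0) bad <- bad | abs(x - med) > mad_threshold * s
    if (any(bad)) {
      x[bad] <- NA_real_
      x <- zoo::na.approx(x, na.rm = FALSE, rule = 2)
    }
    window[[cl]] <- x
    n_rep[cl] <- sum(bad)
  }
  attr(window, "n_replaced") <- n_rep
  attr(window, "qc_low_quality") <- any(n_rep / nrow(window) > 0.10)
  window
}

# Rotation helpers shared by double_rotation and the turbulence generator.
rot_yaw <- function(theta)
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3)
rot_pitch <- function(phi)
  matrix(c(cos(phi), 0, -sin(phi),
           0, 1, 0,
           sin(phi), 0, cos(phi)), 3, 3)

#' Double coordinate rotation
#'
#' Rotates the wind vector so that the mean crosswind and mean vertical wind
#' are zero in the averaging window (yaw then pitch), correcting sensor
#' tilt. The instantaneous wind-speed magnitude is preserved exactly.
#'
#' @param window Data frame with `u`, `v`, `w`.
#' @return The window with rotated winds and attribute `rotation_angles_deg`
#'   (`yaw`, `pitch`).
#' @export
double_rotation <- function(window) {
  m <- c(mean(window$u), mean(window$v), mean(window$w))
  check_that(sqrt(sum(m^2)) > 1e-10,
             "zero mean wind vector: rotation undefined")
  theta <- atan2(m[2], m[1])
  u1 <- window$u * cos(theta) + window$v * sin(theta)
  v1 <- -window$u * sin(theta) + window$v * cos(theta)
  phi <- atan2(mean(window$w), mean(u1))
  u2 <- u1 * cos(phi) + window$w * sin(phi)
  w2 <- -u1 * sin(phi) + window$w * cos(phi)
  window$u <- u2; window$v <- v1; window$w <- w2
  attr(window, "rotation_angles_deg") <-
    c(yaw = theta, pitch = phi) * 180 / pi
  window
}

#' Time-lag correction of scalar series against vertical wind
#'
#' Shifts each scalar series to the integer-sample lag (within
#' `max_lag_s`) that maximises the absolute cross-covariance with `w`.
#' Scalars whose maximum cross-correlation is statistically
#' indistinguishable from zero (|r| < 3/sqrt(n)) are flagged and left
#' unshifted.
#'
#' @param window Data frame with `w` and scalar columns.
#' @param scalars Scalar columns to align (default `T_sonic`, `h2o_gm3`).
#' @param max_lag_s Maximum lag searched, seconds.
#' @param sampling_hz Sampling rate; taken from the window attribute if
#'   absent.
#' @return The window, with attributes `applied_lag_s` (named) and
#'   `qc_low_correlation` (named logical).
#' @export
lag_correct <- function(window, scalars = c("T_sonic", "h2o_gm3"),
                        max_lag_s = 2, sampling_hz = NULL) {
  if (is.null(sampling_hz)) sampling_hz <- attr(window, "sampling_hz")
  check_that(is.numeric(sampling_hz) && sampling_hz > 0,
             "sampling_hz must be supplied (or set as a window attribute)")
  n <- nrow(window)
  max_lag <- as.integer(round(max_lag_s * sampling_hz))
  check_that(max_lag < n, "max_lag_s exceeds the window length")
  scalars <- intersect(scalars, names(window))
  w <- window$w
  lags <- seq(-max_lag, max_lag)
  applied <- numeric(0); lowcor <- logical(0)
  for (cl in scalars) {
    x <- window[[cl]]
    cc <- vapply(lags, function(l) {
      if (l >= 0) stats::cov(w[seq_len(n - l)], x[seq_len(n - l) + l])
      else stats::cov(w[seq_len(n + l) - l], x[seq_len(n + l)])
    }, numeric(1))
    best <- lags[which.max(abs(cc))]
    r <- max(abs(cc)) / (stats::sd(w) * stats::sd(x))
    if (!is.finite(r) || r < 3 / sqrt(n)) {
      lowcor[cl] <- TRUE
      applied[cl] <- 0
      next
    }
    lowcor[cl] <- FALSE
    applied[cl] <- best / sampling_hz
    if (best != 0) {
      shifted <- rep(NA_real_, n)
      if (best > 0) shifted[seq_len(n - best)] <- x[seq_len(n - best) + best]
      else shifted[seq_len(n + best) - best] <- x[seq_len(n + best)]
      window[[cl]] <- zoo::na.approx(shifted, na.rm = FALSE, rule = 2)
    }
  }
  attr(window, "applied_lag_s") <- applied
  attr(window, "qc_low_correlation") <- lowcor
  window
}

# Sonic-to-actual air temperature (K): Ts ~ Ta * (1 + 0.51 q), with q the
# specific humidity from the mean vapour density.  One fixed-point pass is
# ample at ambient humidities.
sonic_to_actual_k <- function(ts_k, h2o_gm3, pressure_kpa) {
  ta <- ts_k
  for (i in 1:3) {
    rho <- air_density(ta - 273.15, pressure_kpa, h2o_gm3)
    q <- (h2o_gm3 / 1000) / rho
    ta <- ts_k / (1 + 0.51 * q)
  }
  ta
}

# Latent heat flux (W/m2) from raw covariances with the WPL density
# adjustment: LE = lambda * (1 + mu*sigma) * (cov(w,rho_v) + rho_v/T *
# cov(w,T)).  Shared with the turbulence generator, which inverts it.
le_from_cov <- function(cov_wq, cov_wt, mean_ts_c, mean_h2o_gm3,
                        pressure_kpa, wpl = TRUE) {
  ta_k <- sonic_to_actual_k(mean_ts_c + 273.15, mean_h2o_gm3, pressure_kpa)
  lambda_jkg <- latent_heat(ta_k - 273.15) * 1e6
  raw <- cov_wq
  if (wpl) {
    rho <- air_density(ta_k - 273.15, pressure_kpa, mean_h2o_gm3)
    rho_d <- rho - mean_h2o_gm3 / 1000
    sigma <- (mean_h2o_gm3 / 1000) / rho_d
    raw <- (1 + .mu_wpl * sigma) * (cov_wq + mean_h2o_gm3 / ta_k * cov_wt)
  }
  lambda_jkg * raw * 1e-3   # g/m2/s -> kg/m2/s
}

h_from_cov <- function(cov_wt, mean_ts_c, mean_h2o_gm3, pressure_kpa) {
  ta_k <- sonic_to_actual_k(mean_ts_c + 273.15, mean_h2o_gm3, pressure_kpa)
  rho <- air_density(ta_k - 273.15, pressure_kpa, mean_h2o_gm3)
  rho * .cp * cov_wt
}

#' Sensible and latent heat fluxes from a processed window
#'
#' Computes `H = rho_a * cp * cov(w', Ts')` and the WPL density-adjusted
#' latent heat flux from `cov(w', rho_v')`, with air density from the
#' ideal-gas law at the measured pressure and the humidity-corrected sonic
#' temperature. The ET depth for the window is `LE * duration / lambda`
#' (mm), clamped at zero for water-budget use; the signed LE is retained.
#'
#' @param window Rotated, lag-corrected window with `w`, `T_sonic` (degC)
#'   and `h2o_gm3` (g/m3).
#' @param pressure_kpa Air pressure, kPa (default 91, the site mean).
#' @param duration_s Averaging period, s (default 1800).
#' @param wpl Apply the WPL density adjustment? (default TRUE)
#' @return One-row data frame: `H_wm2`, `LE_wm2`, `ETa_mm`, `cov_wT`,
#'   `cov_wq`, `air_temp_c`, `qc_flag`.
#' @export
ec_fluxes <- function(window, pressure_kpa = 91, duration_s = 1800,
                      wpl = TRUE) {
  check_that(all(c("w", "T_sonic", "h2o_gm3") %in% names(window)),
             "window needs w, T_sonic, h2o_gm3")
  cov_wt <- stats::cov(window$w, window$T_sonic)
  cov_wq <- stats::cov(window$w, window$h2o_gm3)
  mean_ts <- mean(window$T_sonic)
  mean_q <- mean(window$h2o_gm3)
  h <- h_from_cov(cov_wt, mean_ts, mean_q, pressure_kpa)
  le <- le_from_cov(cov_wq, cov_wt, mean_ts, mean_q, pressure_kpa, wpl)
  ta_k <- sonic_to_actual_k(mean_ts + 273.15, mean_q, pressure_kpa)
  lambda_jkg <- latent_heat(ta_k - 273.15) * 1e6
  qc <- isTRUE(attr(window, "qc_low_quality"))
  data.frame(H_wm2 = h, LE_wm2 = le,
             ETa_mm = max(le, 0) * duration_s / lambda_jkg,
             cov_wT = cov_wt, cov_wq = cov_wq,
             air_temp_c = ta_k - 273.15,
             qc_flag = qc)
}

#' Fluxes from pre-aggregated half-hourly covariances
#'
#' For users without high-frequency records: applies the same density
#' adjustment and ET conversion to stored `cov(w,T)` / `cov(w,rho_v)`
#' values.
#'
#' @param cov_table Data frame with `timestamp`, `cov_wT` (K m/s),
#'   `cov_wq` (g/m2/s), `air_temp_c`, `h2o_gm3`.
#' @param pressure_kpa Air pressure, kPa.
#' @param duration_s Averaging period, s.
#' @param wpl Apply the WPL adjustment?
#' @return Data frame of half-hourly `H_wm2`, `LE_wm2`, `ETa_mm`.
#' @export
ec_fluxes_from_cov <- function(cov_table, pressure_kpa = 91,
                               duration_s = 1800, wpl = TRUE) {
  n <- nrow(cov_table)
  h <- le <- eta <- numeric(n)
  for (i in seq_len(n)) {
    h[i] <- h_from_cov(cov_table$cov_wT[i], cov_table$air_temp_c[i],
                       cov_table$h2o_gm3[i], pressure_kpa)
    le[i] <- le_from_cov(cov_table$cov_wq[i], cov_table$cov_wT[i],
                         cov_table$air_temp_c[i], cov_table$h2o_gm3[i],
                         pressure_kpa, wpl)
    lam <- latent_heat(cov_table$air_temp_c[i]) * 1e6
    eta[i] <- max(le[i], 0) * duration_s / lam
  }
  data.frame(timestamp = cov_table$timestamp, H_wm2 = h, LE_wm2 = le,
             ETa_mm = eta)
}

#' Soil heat flux with storage correction
#'
#' Plates buried at `depth` miss the energy stored in the soil layer above
#' them; the correction adds `Cs * dT/dt * depth`, with the volumetric heat
#' capacity `Cs` built from the mineral fraction and the volumetric water
#' content (`Cs = 1.92*mineral + 2.50*organic + 4.18*theta` MJ/m3/K).
#'
#' @param g_plate Plate heat flux series, W/m2.
#' @param soil_temp Soil temperature series above the plates, degC
#'   (`NULL` omits the storage term with a flag).
#' @param soil_moisture Volumetric water content, fraction (scalar or
#'   series).
#' @param depth Plate depth, m (default 0.08).
#' @param dt_s Timestep, s.
#' @param mineral_fraction Mineral volume fraction of the soil.
#' @param organic_fraction Organic volume fraction.
#' @param cs Volumetric heat capacity override, MJ/m3/K.
#' @return Surface soil heat flux series G, W/m2, with attributes
#'   `storage_omitted` and `cs_mj_m3_k`.
#' @export
soil_heat_flux <- function(g_plate, soil_temp = NULL, soil_moisture = 0.15,
                           depth = 0.08, dt_s = 1800,
                           mineral_fraction = 0.55, organic_fraction = 0,
                           cs = NULL) {
  if (is.null(soil_temp)) {
    return(structure(g_plate, storage_omitted = TRUE, cs_mj_m3_k = NA_real_))
  }
  check_that(length(soil_temp) == length(g_plate),
             "soil_temp and g_plate series must align")
  if (is.null(cs))
    cs <- 1.92 * mineral_fraction + 2.50 * organic_fraction +
      4.18 * soil_moisture
  dT <- c(0, diff(soil_temp))
  storage <- cs * 1e6 * (dT / dt_s) * depth
  structure(g_plate + storage, storage_omitted = FALSE,
            cs_mj_m3_k = if (length(cs) == 1) cs else NA_real_)
}

#' FAO-56 Penman-Monteith reference evapotranspiration
#'
#' Reference ET of clipped well-watered grass. The hourly form uses the
#' aerodynamic coefficient 37 per hour (scaled by `dt_hours` for sub-hourly
#' intervals); the daily form uses 900. Radiation terms are per interval
#' (MJ/m2).
#'
#' @param rn Net radiation, MJ/m2 per interval.
#' @param g Soil heat flux, MJ/m2 per interval.
#' @param temp_c Mean air temperature, degC.
#' @param rh_pct Relative humidity, percent (0-100).
#' @param u2 Wind speed at 2 m, m/s.
#' @param pressure_kpa Air pressure, kPa.
#' @param timestep `"hourly"` (also half-hourly via `dt_hours`) or
#'   `"daily"`.
#' @param dt_hours Interval length in hours for the hourly form.
#' @param clamp_negative Floor ETo at zero (default TRUE).
#' @return ETo, mm per interval.
#' @export
penman_monteith_eto <- function(rn, g, temp_c, rh_pct, u2,
                                pressure_kpa = 91,
                                timestep = c("hourly", "daily"),
                                dt_hours = 1, clamp_negative = TRUE) {
  timestep <- match.arg(timestep)
  check_that(all(rh_pct >= 0 & rh_pct <= 100, na.rm = TRUE),
             "relative humidity must be within [0, 100]")
  delta <- svp_slope(temp_c)
  gam <- psychrometric_gamma(pressure_kpa)
  es <- sat_vapour_pressure(temp_c)
  ea <- es * rh_pct / 100
  cn <- if (timestep == "hourly") 37 * dt_hours else 900
  num <- 0.408 * delta * (rn - g) +
    gam * cn / (temp_c + 273) * u2 * (es - ea)
  den <- delta + gam * (1 + 0.34 * u2)
  eto <- num / den
  if (clamp_negative) eto <- pmax(eto, 0)
  eto
}

# Simple net-radiation and soil-heat-flux estimators used when measured Rn/G
# are unavailable: canopy albedo 0.23 (net shortwave 0.77 Rs) minus a fixed
# semi-arid net-longwave loss; G as the FAO daytime/nighttime fraction of Rn.
net_radiation_estimate <- function(solar_wm2) 0.77 * solar_wm2 - 45
ground_flux_estimate <- function(rn_wm2, daytime) {
  ifelse(daytime, 0.1, 0.5) * rn_wm2
}

#' Half-hourly and daily ETo from a weather table
#'
#' Computes interval ETo with the FAO-56 hourly form (interval length taken
#' from the timestamps) and aggregates daily ETo as the sum of interval
#' values. Net radiation and soil heat flux are taken from `rn_wm2` /
#' `g_wm2` columns when present, otherwise estimated from solar radiation.
#'
#' @param weather Half-hourly weather table ([generate_weather()] layout).
#' @return List with `interval` (timestamp, eto_mm) and `daily` (date,
#'   eto_mm).
#' @export
eto_from_weather <- function(weather) {
  dt_s <- as.numeric(stats::median(diff(as.numeric(weather$timestamp))))
  dt_h <- dt_s / 3600
  rn <- if ("rn_wm2" %in% names(weather)) weather$rn_wm2
        else net_radiation_estimate(weather$solar_wm2)
  g <- if ("g_wm2" %in% names(weather)) weather$g_wm2
       else ground_flux_estimate(rn, weather$solar_wm2 > 10)
  rn_mj <- rn * dt_s / 1e6
  g_mj <- g * dt_s / 1e6
  eto <- penman_monteith_eto(rn_mj, g_mj, weather$air_temp_c,
                             weather$rh_pct, weather$wind_ms,
                             weather$pressure_kpa, timestep = "hourly",
                             dt_hours = dt_h)
  date <- interval_date(weather$timestamp, dt_s)
  daily <- stats::aggregate(eto, list(date = date), sum)
  names(daily)[2] <- "eto_mm"
  daily$date <- as.Date(daily$date)
  list(interval = data.frame(timestamp = weather$timestamp, eto_mm = eto),
       daily = daily)
}

#' Crop coefficient as the origin-constrained slope of ETa on ETo
#'
#' `Kc = sum(ETa * ETo) / sum(ETo^2)`: the least-squares slope through the
#' origin of daily actual against reference evapotranspiration.
#'
#' @param eta_daily Daily actual ET, mm/day.
#' @param eto_daily Daily reference ET, mm/day (paired).
#' @param min_pairs Minimum number of paired days (default 10).
#' @return A `kc_estimate` list: `slope`, `se`, `n_days`, `r_squared`.
#' @export
kc_estimate <- function(eta_daily, eto_daily, min_pairs = 10) {
  check_that(length(eta_daily) == length(eto_daily),
             "series must be paired")
  ok <- is.finite(eta_daily) & is.finite(eto_daily)
  eta <- eta_daily[ok]; eto <- eto_daily[ok]
  check_that(length(eta) >= min_pairs,
             sprintf("need at least %d paired days", min_pairs))
  check_that(any(eto != 0), "all reference ET values are zero")
  slope <- sum(eta * eto) / sum(eto^2)
  res <- eta - slope * eto
  n <- length(eta)
  se <- sqrt(sum(res^2) / (n - 1) / sum(eto^2))
  r2 <- 1 - sum(res^2) / sum(eta^2)
  structure(list(slope = slope, se = se, n_days = n, r_squared = r2),
            class = "kc_estimate")
}

#' @export
print.kc_estimate <- function(x, ...) {
  cat(sprintf("Crop coefficient Kc = %.3f (SE %.3f, n = %d days)\n",
              x$slope, x$se, x$n_days))
  invisible(x)
}
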