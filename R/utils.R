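# Shared physical constants and small helpers used across modules.

# Dry-air gas constant, J/kg/K
.Rd <- 287.04
# Water-vapour gas constant, J/kg/K
.Rv <- 461.5
# Specific heat of dry air at constant pressure, J/kg/K
.cp <- 1005
# Ratio of molar masses dry air / water vapour (WPL mu)
.mu_wpl <- 28.964 / 18.016
# Density of liquid water, kg/m3
.rho_w <- 1000

#' Latent heat of vaporisation of water
#'
#' Linear function of air temperature (MJ/kg), appropriate for records that
#' span a wide temperature range; at 20 degC it equals the familiar
#' 2.45 MJ/kg.
#'
#' @param temp_c Air temperature, degC.
#' @return Latent heat, MJ/kg.
#' @export
latent_heat <- function(temp_c) {
  2.501 - 2.361e-3 * temp_c
}

#' Saturation vapour pressure (FAO-56 / Tetens form)
#'
#' @param temp_c Air temperature, degC.
#' @return Saturation vapour pressure, kPa.
#' @export
sat_vapour_pressure <- function(temp_c) {
  0.6108 * exp(17.27 * temp_c / (temp_c + 237.3))
}

# Slope of the saturation vapour pressure curve, kPa/degC
svp_slope <- function(temp_c) {
  4098 * sat_vapour_pressure(temp_c) / (temp_c + 237.3)^2
}

# Psychrometric constant from air pressure, kPa/degC
psychrometric_gamma <- function(pressure_kpa) {
  0.000665 * pressure_kpa
}

#' Moist air density from the ideal-gas law
#'
#' @param temp_c Air temperature, degC.
#' @param pressure_kpa Air pressure, kPa.
#' @param vapour_density_gm3 Water-vapour density, g/m3 (0 for dry air).
#' @return Air density, kg/m3.
#' @export
air_density <- function(temp_c, pressure_kpa, vapour_density_gm3 = 0) {
  t_k <- temp_c + 273.15
  e_pa <- vapour_density_gm3 / 1000 * .Rv * t_k   # vapour partial pressure, Pa
  rho_d <- (pressure_kpa * 1000 - e_pa) / (.Rd * t_k)
  rho_d + vapour_density_gm3 / 1000
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stopifnot with a custom message
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Month index (1-12) of POSIXct/Date vectors, UTC
month_of <- function(t) as.integer(format(t, "%m", tz = "UTC"))

# Calendar date of an interval-ending timestamp: the instant t belongs to
# the interval (t - dt, t], so midnight 00:00 closes the previous day.
interval_date <- function(t, dt_s) {
  as.Date(t - 1, tz = "UTC")
}
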