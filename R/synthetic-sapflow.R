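# Ground-truth sap-velocity curves, synthetic heat-pulse logger output and
# a synthetic tree inventory.  The heat-pulse generator is the exact inverse
# of the heat-ratio velocity formula, so with zero noise the processing chain
# must return the prescribed velocities to numerical precision.

#' Default diurnal shape for sap velocity
#'
#' 48 nonnegative half-hourly weights with mean 1: a daytime bell over
#' ~06:30-19:00 plus a small nocturnal baseline (desert trees sustain low
#' night-time flow).
#'
#' @return Numeric vector of length 48, mean exactly 1.
#' @export
diurnal_shape_default <- function() {
  hour <- (seq_len(48) - 0.5) / 2
  w <- 0.08 + pmax(0, sin(pi * (hour - 6.5) / 12.5))^1.4
  w / mean(w)
}

#' Ground-truth sap velocity curve for one tree
#'
#' @param tree_id Tree identifier.
#' @param base_velocity Daily-mean heat-pulse velocity, cm/h (>= 0).
#' @param diurnal_shape 48 nonnegative half-hourly weights; normalised to
#'   mean 1 so `base_velocity` stays the daily mean.
#' @param seasonal_multiplier Length-12 per-month factor (default all 1).
#' @param noise_sd Additive velocity noise SD, cm/h, applied per sample.
#' @return A `sap_velocity_curve` list.
#' @export
sap_velocity_curve <- function(tree_id, base_velocity = 15,
                               diurnal_shape = diurnal_shape_default(),
                               seasonal_multiplier = rep(1, 12),
                               noise_sd = 0) {
  check_that(base_velocity >= 0, "base_velocity must be >= 0")
  check_that(length(diurnal_shape) == 48 && all(diurnal_shape >= 0),
             "diurnal_shape must be 48 nonnegative weights")
  check_that(length(seasonal_multiplier) == 12 && all(seasonal_multiplier >= 0),
             "seasonal_multiplier must be 12 nonnegative factors")
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  if (mean(diurnal_shape) > 0)
    diurnal_shape <- diurnal_shape / mean(diurnal_shape)
  structure(list(tree_id = as.character(tree_id),
                 base_velocity = base_velocity,
                 diurnal_shape = diurnal_shape,
                 seasonal_multiplier = seasonal_multiplier,
                 noise_sd = noise_sd),
            class = "sap_velocity_curve")
}

#' True heat-pulse velocity implied by a curve at given timestamps
#'
#' @param curve A [sap_velocity_curve()].
#' @param timestamp POSIXct vector (interval-ending, UTC).
#' @return Velocity, cm/h.
#' @export
true_velocity <- function(curve, timestamp) {
  mid <- timestamp - 900
  slot <- as.integer(format(mid, "%H", tz = "UTC")) * 2L +
    as.integer(format(mid, "%M", tz = "UTC")) %/% 30L + 1L
  curve$base_velocity * curve$diurnal_shape[slot] *
    curve$seasonal_multiplier[month_of(mid)]
}

#' Generate synthetic heat-pulse logger records
#'
#' Emits, per half hour and thermocouple depth, downstream/upstream
#' temperature rises whose ratio is `exp(Vh * x / (k * 3600))` -- the exact
#' inverse of the heat-ratio velocity formula -- with optional additive
#' velocity noise.
#'
#' @param curve A [sap_velocity_curve()].
#' @param probe A [probe_geometry()].
#' @param start Start date.
#' @param days Number of days (>= 1).
#' @param seed Seed for the noise stream.
#' @param base_rise Downstream reference temperature rise v2, degC.
#' @return Data frame with columns `tree_id`, `timestamp`, `depth_cm`,
#'   `v1_C`, `v2_C` (the logger CSV layout).
#' @export
generate_heat_pulse_series <- function(curve, probe = probe_geometry(),
                                       start = as.Date("2017-01-01"),
                                       days = 7, seed = 1L,
                                       base_rise = 0.4) {
  stopifnot(inherits(curve, "sap_velocity_curve"),
            inherits(probe, "probe_geometry"))
  days <- as.integer(days)
  check_that(days >= 1, "days must be >= 1")
  t0 <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = "UTC")
  timestamp <- t0 + seq_len(48L * days) * 1800
  vh <- true_velocity(curve, timestamp)
  nd <- length(probe$depths)
  out <- with_seed(seed, {
    long_vh <- rep(vh, times = nd) +
      if (curve$noise_sd > 0)
        stats::rnorm(length(vh) * nd, sd = curve$noise_sd) else 0
    ratio <- exp(long_vh * probe$x / (probe$k * 3600))
    data.frame(tree_id = curve$tree_id,
               timestamp = rep(timestamp, times = nd),
               depth_cm = rep(probe$depths, each = length(timestamp)),
               v1_C = base_rise * ratio,
               v2_C = base_rise)
  })
  out[order(out$timestamp, out$depth_cm), , drop = FALSE]
}

# Default generating allometry for the synthetic inventory:
# sapwood_area (cm2) = intercept + slope * stem_diameter (cm).
true_allometry_default <- function() list(intercept = -6, slope = 3.2)

#' Generate a synthetic tree inventory
#'
#' Stem diameters are uniform within `diameter_range`; habitats are drawn
#' from `habitat_mix`; true sapwood areas follow a known linear allometry
#' (optionally with noise) so that [fit_allometry()] can be checked against
#' the generating coefficients.
#'
#' @param n Number of trees (>= 1).
#' @param habitat_mix Named proportions over habitats (sums to 1).
#' @param diameter_range Stem diameter range at 60 cm height, cm.
#' @param allometry List with `intercept` (cm2) and `slope` (cm2/cm).
#' @param area_noise_sd SD of additive noise on sapwood area, cm2.
#' @param canopy_area Canopy area per tree, m2.
#' @param seed Integer seed.
#' @return Data frame of tree records (`tree_id`, `site`, `habitat`,
#'   `stem_diameter_cm`, `bark_depth_cm`, `sapwood_depth_cm`,
#'   `sapwood_area_cm2`, `canopy_area_m2`).
#' @export
generate_tree_inventory <- function(n, habitat_mix = c(floodplain = 0.5,
                                                       dryland = 0.5),
                                    diameter_range = c(6, 30),
                                    allometry = true_allometry_default(),
                                    area_noise_sd = 0, canopy_area = 2,
                                    seed = 1L) {
  n <- as.integer(n)
  check_that(n >= 1, "n must be >= 1")
  check_that(length(diameter_range) == 2 &&
               diameter_range[2] > diameter_range[1] && diameter_range[1] > 0,
             "diameter_range must be an increasing positive pair")
  check_that(abs(sum(habitat_mix) - 1) < 1e-9,
             "habitat_mix proportions must sum to 1")
  with_seed(seed, {
    d <- stats::runif(n, diameter_range[1], diameter_range[2])
    habitat <- sample(names(habitat_mix), n, replace = TRUE,
                      prob = habitat_mix)
    area <- allometry$intercept + allometry$slope * d
    if (area_noise_sd > 0) area <- area + stats::rnorm(n, sd = area_noise_sd)
    area <- pmax(area, 1)
    site <- paste0(ifelse(habitat == "floodplain", "FP", "DL"),
                   1L + seq_len(n) %% 2L)
    data.frame(tree_id = sprintf("T%02d", seq_len(n)),
               site = site, habitat = habitat,
               stem_diameter_cm = d,
               bark_depth_cm = 0.5,
               sapwood_depth_cm = pmin(0.22 * d, 4.5),
               sapwood_area_cm2 = area,
               canopy_area_m2 = canopy_area)
  })
}
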