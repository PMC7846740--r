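# Heat-ratio-method (HRM) sap-flow processing: heat-pulse velocity from
# temperature-rise ratios, wound correction, sapwood allometry, whole-tree
# volumetric flow via radial annuli, and daily aggregation.

#' Heat-pulse probe geometry
#'
#' @param k Thermal diffusivity of fresh wood, cm2/s (nominal 2.5e-3).
#' @param x Heater-to-thermocouple spacing, cm (~0.5).
#' @param depths Thermocouple depths below the cambium, cm, strictly
#'   increasing (default 0.8 and 1.1 cm).
#' @param wound_width Drilled wound width, cm, used by [wound_correct()].
#' @return A `probe_geometry` list.
#' @export
probe_geometry <- function(k = 2.5e-3, x = 0.5, depths = c(0.8, 1.1),
                           wound_width = 0.20) {
  check_that(k > 0, "thermal diffusivity k must be > 0")
  check_that(x > 0, "probe spacing x must be > 0")
  check_that(length(depths) >= 1 && all(depths > 0) &&
               all(diff(depths) > 0),
             "depths must be positive and strictly increasing")
  structure(list(k = k, x = x, depths = depths, wound_width = wound_width),
            class = "probe_geometry")
}

#' Heat-pulse velocity from upstream/downstream temperature rises
#'
#' `Vh = (k / x) * ln(v1 / v2) * 3600` (cm/h). The sign is preserved:
#' negative values indicate reverse flow, which the heat-ratio method is
#' designed to resolve. Non-positive temperature rises leave the log-ratio
#' undefined; those samples return `NA` and are counted in the
#' `n_invalid` attribute.
#'
#' @param v1 Downstream temperature rise, degC.
#' @param v2 Upstream temperature rise, degC.
#' @param probe A [probe_geometry()].
#' @return Velocity vector, cm/h, with attribute `n_invalid`.
#' @export
heat_pulse_velocity <- function(v1, v2, probe = probe_geometry()) {
  stopifnot(inherits(probe, "probe_geometry"), length(v1) == length(v2))
  bad <- !is.finite(v1) | !is.finite(v2) | v1 <= 0 | v2 <= 0
  vh <- rep(NA_real_, length(v1))
  # log(v1) - log(v2) rather than log(v1/v2): antisymmetric to the bit
  vh[!bad] <- (probe$k / probe$x) * (log(v1[!bad]) - log(v2[!bad])) * 3600
  structure(vh, n_invalid = sum(bad))
}

#' Wound-correction coefficient table
#'
#' Cubic wound-correction polynomials `Vc = b*Vh + c*Vh^2 + d*Vh^3` keyed by
#' wound width, following the published numerical solutions for the
#' heat-ratio probe configuration (Swanson-type numerical model as tabulated
#' by Burgess and co-workers): the linear term grows from ~1.7 to ~2.7 as
#' the wound widens from 0.17 to 0.30 cm, with small higher-order terms.
#' Override per-deployment values via the `coefficients` argument of
#' [wound_correct()].
#'
#' @return Data frame with columns `wound_width`, `a`, `b`, `c`, `d`.
#' @export
wound_coefficients <- function() {
  data.frame(
    wound_width = c(0.17, 0.20, 0.22, 0.24, 0.26, 0.28, 0.30),
    a = 0,
    b = c(1.7283, 1.8905, 2.0038, 2.1474, 2.3045, 2.4813, 2.6610),
    c = c(-0.0012, -0.0124, -0.0187, -0.0238, -0.0296, -0.0363, -0.0435),
    d = c(0.0002, 0.0010, 0.0014, 0.0018, 0.0021, 0.0025, 0.0029)
  )
}

#' Wound-correct heat-pulse velocities
#'
#' Applies `Vc = a + b*Vh + c*Vh^2 + d*Vh^3` with coefficients looked up by
#' wound width (reverse-flow velocities are corrected antisymmetrically so
#' the correction never flips sign).
#'
#' @param vh Heat-pulse velocity, cm/h.
#' @param wound_width Wound width, cm; must match a tabulated width.
#' @param coefficients Optional override: numeric vector `c(a, b, c)` or
#'   `c(a, b, c, d)`.
#' @return Corrected velocity, cm/h.
#' @export
wound_correct <- function(vh, wound_width = 0.20, coefficients = NULL) {
  if (is.null(coefficients)) {
    tab <- wound_coefficients()
    i <- which(abs(tab$wound_width - wound_width) < 1e-8)
    if (length(i) != 1)
      stop(sprintf(
        "wound_width %.3f cm is not tabulated; supported widths: %s cm",
        wound_width, paste(format(tab$wound_width), collapse = ", ")),
        call. = FALSE)
    coefficients <- c(tab$a[i], tab$b[i], tab$c[i], tab$d[i])
  }
  if (length(coefficients) == 3) coefficients <- c(coefficients, 0)
  check_that(length(coefficients) == 4,
             "coefficients must be c(a, b, c) or c(a, b, c, d)")
  a <- coefficients[1]; b <- coefficients[2]
  cc <- coefficients[3]; d <- coefficients[4]
  s <- sign(vh); av <- abs(vh)
  s * (a + b * av + cc * av^2 + d * av^3)
}

#' Fit the sapwood-area vs stem-diameter allometry
#'
#' Ordinary least squares of sapwood area (cm2) on stem diameter (cm), used
#' to assign sapwood areas to uninstrumented trees.
#'
#' @param stem_diameter Stem diameters at 60 cm height, cm.
#' @param sapwood_area Sapwood areas, cm2.
#' @return An `allometry_model` list with `intercept`, `slope`, `r_squared`,
#'   `n`, and the underlying `lm` fit.
#' @export
fit_allometry <- function(stem_diameter, sapwood_area) {
  check_that(length(stem_diameter) == length(sapwood_area),
             "inputs must have equal length")
  check_that(length(stem_diameter) >= 3, "need at least 3 (diameter, area) pairs")
  check_that(length(unique(stem_diameter)) >= 2,
             "stem diameters are all identical: degenerate design")
  fit <- stats::lm(sapwood_area ~ stem_diameter)
  # summary.lm warns on exact fits; a perfect line is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = sm$r.squared,
                 n = length(stem_diameter), fit = fit),
            class = "allometry_model")
}

#' Predict sapwood area from stem diameter
#'
#' @param model An [fit_allometry()] result.
#' @param stem_diameter Stem diameter, cm.
#' @return Sapwood area, cm2, clamped above zero.
#' @export
predict_sapwood_area <- function(model, stem_diameter) {
  stopifnot(inherits(model, "allometry_model"))
  pmax(model$intercept + model$slope * stem_diameter, 1e-6)
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf(
    "Sapwood-area allometry: area = %.3f + %.3f * diameter (R2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Process heat-pulse samples to per-depth sap velocities
#'
#' Computes the heat-pulse velocity per record and (optionally) the wound
#' correction. Invalid samples (non-positive temperature rises) become `NA`
#' velocities; the count is attached as attribute `n_invalid`.
#'
#' @param samples Logger table with `tree_id`, `timestamp`, `depth_cm`,
#'   `v1_C`, `v2_C`.
#' @param probe A [probe_geometry()].
#' @param wound Apply the wound correction? (default TRUE).
#' @param coefficients Optional wound-coefficient override.
#' @return The input table with `vh_cmh` (raw) and `vc_cmh` (corrected).
#' @export
sap_velocity_table <- function(samples, probe = probe_geometry(),
                               wound = TRUE, coefficients = NULL) {
  need <- c("tree_id", "timestamp", "depth_cm", "v1_C", "v2_C")
  miss <- setdiff(need, names(samples))
  check_that(length(miss) == 0,
             paste("missing columns:", paste(miss, collapse = ", ")))
  vh <- heat_pulse_velocity(samples$v1_C, samples$v2_C, probe)
  samples$vh_cmh <- as.numeric(vh)
  samples$vc_cmh <- if (wound)
    wound_correct(samples$vh_cmh, probe$wound_width, coefficients)
  else samples$vh_cmh
  attr(samples, "n_invalid") <- attr(vh, "n_invalid")
  samples
}

#' Sapwood annulus areas per thermocouple depth
#'
#' The sapwood ring (outer boundary at the cambium, inner boundary at the
#' visually determined sapwood depth) is split at the midpoints between
#' thermocouple depths into concentric annuli; each annulus carries its
#' probe's velocity. Areas are normalised so they sum to the tree's sapwood
#' area. With no usable stem geometry the sapwood area is split equally.
#'
#' @param tree One tree record (list or single data-frame row) with
#'   `sapwood_area_cm2` and, ideally, `stem_diameter_cm`, `bark_depth_cm`,
#'   `sapwood_depth_cm`.
#' @param probe A [probe_geometry()].
#' @return Numeric vector of annulus areas (cm2), one per depth.
#' @export
sapwood_annuli <- function(tree, probe = probe_geometry()) {
  area <- tree$sapwood_area_cm2
  check_that(is.numeric(area) && area > 0, "tree needs sapwood_area_cm2 > 0")
  nd <- length(probe$depths)
  if (nd == 1) return(area)
  dia <- tree$stem_diameter_cm
  bark <- if (!is.null(tree$bark_depth_cm)) tree$bark_depth_cm else 0.5
  sw <- tree$sapwood_depth_cm
  if (is.null(dia) || is.null(sw) || !is.finite(dia) || !is.finite(sw) ||
      dia <= 0 || sw <= 0)
    return(rep(area / nd, nd))
  r_cambium <- dia / 2 - bark
  if (r_cambium <= 0) return(rep(area / nd, nd))
  cuts <- c(0, probe$depths[-nd] + diff(probe$depths) / 2, max(sw, max(probe$depths)))
  radii <- pmax(r_cambium - cuts, 0)
  ann <- pi * (radii[-length(radii)]^2 - radii[-1]^2)
  if (sum(ann) <= 0) return(rep(area / nd, nd))
  ann * (area / sum(ann))
}

#' Whole-tree volumetric sap flow from per-depth velocities
#'
#' `flow (L/h) = sum_depth velocity (cm/h) * annulus area (cm2) * 1e-3`.
#' At timestamps where some depths are invalid, the area-weighted mean of
#' the valid velocities is applied over the full sapwood area; where all
#' depths are invalid the timestamp is a gap (`NA`).
#'
#' @param velocities Long table with `timestamp`, `depth_cm` and a velocity
#'   column (`vc_cmh` by default, falling back to `vh_cmh`).
#' @param tree One tree record (needs `sapwood_area_cm2`, geometry optional).
#' @param probe A [probe_geometry()].
#' @return Data frame `timestamp`, `flow_lph`.
#' @export
tree_sap_flow <- function(velocities, tree, probe = probe_geometry()) {
  vcol <- if ("vc_cmh" %in% names(velocities)) "vc_cmh" else "vh_cmh"
  check_that(vcol %in% names(velocities),
             "velocities needs a vc_cmh or vh_cmh column")
  areas <- sapwood_annuli(tree, probe)
  names(areas) <- as.character(probe$depths)
  v <- velocities[[vcol]]
  a <- areas[as.character(velocities$depth_cm)]
  check_that(!anyNA(names(a)) && !anyNA(a),
             "depth_cm values must match the probe depths")
  ok <- is.finite(v)
  tsec <- as.numeric(velocities$timestamp)
  num <- tapply(ifelse(ok, v * a, 0), tsec, sum)
  den <- tapply(ifelse(ok, a, 0), tsec, sum)
  flow <- ifelse(den > 0, num / den * sum(areas) * 1e-3, NA_real_)
  ts <- as.POSIXct(as.numeric(names(num)), origin = "1970-01-01", tz = "UTC")
  out <- data.frame(timestamp = ts, flow_lph = as.numeric(flow))
  out[order(out$timestamp), , drop = FALSE]
}

#' Aggregate an hourly/half-hourly flow series to daily tree water use
#'
#' Gaps up to `max_gap_hours` are filled by linear interpolation; the QC
#' fraction is the share of intervals valid after gap-filling. Days whose QC
#' falls below `qc_threshold` are dropped from the output (their count is in
#' attribute `n_dropped_days`). Timestamps are interval-ending local calendar
#' time. Negative daily totals (sustained reverse flow) are retained.
#'
#' @param flow Data frame `timestamp`, `flow_lph` on a regular grid.
#' @param tree Tree record providing `canopy_area_m2` (default 2 m2).
#' @param max_gap_hours Longest gap filled by interpolation, hours.
#' @param qc_threshold Minimum valid fraction for a day to be reported.
#' @return Data frame `tree_id`, `date`, `volume_l`, `depth_mm`, `qc` with
#'   attribute `n_dropped_days`.
#' @export
daily_aggregate <- function(flow, tree = list(tree_id = "tree",
                                              canopy_area_m2 = 2),
                            max_gap_hours = 2, qc_threshold = 0.8) {
  if (nrow(flow) == 0) {
    out <- data.frame(tree_id = character(), date = as.Date(character()),
                      volume_l = numeric(), depth_mm = numeric(),
                      qc = numeric())
    attr(out, "n_dropped_days") <- 0L
    return(out)
  }
  flow <- flow[order(flow$timestamp), , drop = FALSE]
  dt <- as.numeric(stats::median(diff(as.numeric(flow$timestamp))))
  check_that(is.finite(dt) && dt > 0, "cannot infer a positive timestep")
  # complete the regular grid so missing rows count as gaps
  grid <- seq(min(flow$timestamp), max(flow$timestamp), by = dt)
  full <- merge(data.frame(timestamp = grid), flow, all.x = TRUE)
  filled <- zoo::na.approx(full$flow_lph, x = as.numeric(full$timestamp),
                           maxgap = max_gap_hours * 3600 / dt, na.rm = FALSE)
  date <- interval_date(full$timestamp, dt)
  canopy <- if (!is.null(tree$canopy_area_m2)) tree$canopy_area_m2 else 2
  check_that(canopy > 0, "canopy_area_m2 must be > 0")
  vol <- tapply(filled * dt / 3600, date, sum)        # NA if any gap remains
  qc <- tapply(!is.na(filled), date, mean)
  n_iv <- tapply(filled, date, length)
  # partial first/last days: scale qc by expected interval count
  per_day <- 86400 / dt
  qc <- qc * pmin(1, as.numeric(n_iv) / per_day)
  vol_sum <- tapply(ifelse(is.na(filled), 0, filled) * dt / 3600, date, sum)
  out <- data.frame(tree_id = if (!is.null(tree$tree_id)) tree$tree_id else "tree",
                    date = as.Date(names(vol)),
                    volume_l = as.numeric(ifelse(is.na(vol), vol_sum, vol)),
                    depth_mm = NA_real_,
                    qc = as.numeric(qc))
  out$depth_mm <- out$volume_l / canopy   # 1 L/m2 == 1 mm
  keep <- out$qc >= qc_threshold
  dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped_days") <- dropped
  out
}

#' Per-habitat and overall water-use summary
#'
#' Per-tree period means are computed first, then the unweighted mean and SD
#' across trees within each habitat; the overall row is the mean across all
#' trees. Values are reported both as L/tree/day and, via canopy area, as
#' mm/day. A habitat with a single tree reports SD 0 with `sd_defined
#' = FALSE`.
#'
#' @param daily [daily_aggregate()] output for several trees (bound rows).
#' @param trees Tree inventory with `tree_id`, `habitat`, `canopy_area_m2`.
#' @return Data frame with one row per habitat plus an `all` row.
#' @export
habitat_summary <- function(daily, trees) {
  check_that(all(c("tree_id", "volume_l") %in% names(daily)),
             "daily needs tree_id and volume_l")
  check_that(all(c("tree_id", "habitat") %in% names(trees)),
             "trees needs tree_id and habitat")
  known <- c("floodplain", "dryland")
  bad <- setdiff(unique(trees$habitat), known)
  if (length(bad) > 0)
    stop("unknown habitat label(s): ", paste(bad, collapse = ", "),
         " (expected ", paste(known, collapse = " | "), ")", call. = FALSE)
  per_tree <- stats::aggregate(volume_l ~ tree_id, data = daily, FUN = mean)
  per_tree <- merge(per_tree, trees[, c("tree_id", "habitat",
                                        "canopy_area_m2")], by = "tree_id")
  per_tree$depth_mm <- per_tree$volume_l / per_tree$canopy_area_m2
  summarise <- function(df, label) {
    n <- nrow(df)
    sdv <- if (n > 1) stats::sd(df$volume_l) else 0
    data.frame(group = label, n_trees = n,
               mean_l_day = mean(df$volume_l), sd_l_day = sdv,
               mean_mm_day = mean(df$depth_mm),
               sd_mm_day = if (n > 1) stats::sd(df$depth_mm) else 0,
               sd_defined = n > 1)
  }
  rows <- lapply(split(per_tree, per_tree$habitat),
                 function(df) summarise(df, df$habitat[1]))
  out <- do.call(rbind, c(rows, list(summarise(per_tree, "all"))))
  rownames(out) <- NULL
  out
}

#' Seasonal water-use summary
#'
#' Restricts daily records to each month window and applies
#' [habitat_summary()]. Empty windows are flagged, not errors.
#'
#' @param daily Bound [daily_aggregate()] output.
#' @param trees Tree inventory.
#' @param seasons Named list of month-index vectors
#'   (default dry Jan-Mar, rainy Jul-Sep).
#' @return Data frame of per-season summaries with columns `season` and
#'   `empty` prepended.
#' @export
seasonal_summary <- function(daily, trees,
                             seasons = list(dry = 1:3, rainy = 7:9)) {
  check_that(length(seasons) >= 1 && all(lengths(seasons) >= 1),
             "seasons must be a non-empty list of month windows")
  mon <- as.integer(format(daily$date, "%m"))
  out <- lapply(names(seasons), function(s) {
    sub <- daily[mon %in% seasons[[s]], , drop = FALSE]
    if (nrow(sub) == 0) {
      data.frame(season = s, empty = TRUE, group = NA_character_,
                 n_trees = 0L, mean_l_day = NA_real_, sd_l_day = NA_real_,
                 mean_mm_day = NA_real_, sd_mm_day = NA_real_,
                 sd_defined = FALSE)
    } else {
      cbind(season = s, empty = FALSE, habitat_summary(sub, trees))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Build a stem size-class table from instrumented trees
#'
#' Assigns instrumented trees to diameter classes; the representative flow
#' per class defaults to the mean of the per-tree mean daily volumes in the
#' class ("mean" mode) or to the allometry-style regression of flow on
#' diameter evaluated at the class midpoint ("regression" mode). Class
#' proportions describe the stand's diameter distribution.
#'
#' @param daily Bound [daily_aggregate()] output.
#' @param trees Tree inventory with `stem_diameter_cm`.
#' @param breaks Diameter class breaks, cm.
#' @param proportions Stand proportions per class (default: share of
#'   inventory trees per class).
#' @param mode `"mean"` or `"regression"`.
#' @return Data frame `diameter_lo`, `diameter_hi`, `proportion`,
#'   `representative_flow_l_day`.
#' @export
size_class_table <- function(daily, trees, breaks = c(0, 10, 20, 40),
                             proportions = NULL, mode = c("mean",
                                                          "regression")) {
  mode <- match.arg(mode)
  per_tree <- stats::aggregate(volume_l ~ tree_id, data = daily, FUN = mean)
  per_tree <- merge(per_tree, trees[, c("tree_id", "stem_diameter_cm")],
                    by = "tree_id")
  cls <- cut(per_tree$stem_diameter_cm, breaks, right = FALSE)
  lev <- levels(cls)
  if (is.null(proportions)) {
    all_cls <- cut(trees$stem_diameter_cm, breaks, right = FALSE)
    proportions <- as.numeric(table(all_cls)) / nrow(trees)
  }
  check_that(length(proportions) == length(lev),
             "proportions must have one entry per class")
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  predictable <- length(unique(per_tree$stem_diameter_cm)) >= 2
  reg_flow <- if (predictable) {
    fit <- stats::lm(volume_l ~ stem_diameter_cm, data = per_tree)
    pmax(as.numeric(stats::predict(fit,
                                   data.frame(stem_diameter_cm = mids))), 0)
  } else rep(mean(per_tree$volume_l), length(mids))
  rep_flow <- if (mode == "mean") {
    rf <- as.numeric(tapply(per_tree$volume_l, cls, mean))
    # classes without an instrumented tree fall back to the regression
    rf[is.na(rf)] <- reg_flow[is.na(rf)]
    rf
  } else reg_flow
  data.frame(diameter_lo = breaks[-length(breaks)],
             diameter_hi = breaks[-1],
             proportion = proportions,
             representative_flow_l_day = rep_flow)
}

#' Stand transpiration from a stem size-class table
#'
#' The stand-mean tree flow is the proportion-weighted sum of the class
#' representative flows, `Qbar = sum(p_c * Q_c)` (L/day). In
#' canopy-normalised mode the depth equivalent is `Qbar / canopy_area`
#' (mm/day over the canopy); in density mode it is `Qbar * stand_density`
#' (trees/m2, giving L/m2/day == mm/day of ground area).
#'
#' @param classes A [size_class_table()]-style table (classes with
#'   `proportion` and `representative_flow_l_day`).
#' @param mode `"canopy"` or `"density"`.
#' @param canopy_area Mean canopy area per tree, m2 (canopy mode).
#' @param stand_density Stand density, trees/m2 (density mode).
#' @return Stand transpiration, mm/day, with attribute `mean_flow_l_day`.
#' @export
stand_transpiration <- function(classes, mode = c("canopy", "density"),
                                canopy_area = 2, stand_density = NULL) {
  mode <- match.arg(mode)
  p <- classes$proportion
  q <- classes$representative_flow_l_day
  check_that(abs(sum(p) - 1) <= 1e-9, "class proportions must sum to 1")
  check_that(!anyNA(q), "every class needs a representative flow")
  qbar <- sum(p * q)
  depth <- if (mode == "canopy") {
    check_that(canopy_area > 0, "canopy_area must be > 0")
    qbar / canopy_area
  } else {
    check_that(is.numeric(stand_density) && stand_density > 0,
               "density mode needs stand_density > 0 (trees/m2)")
    qbar * stand_density
  }
  structure(depth, mean_flow_l_day = qbar)
}
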