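# Multiple linear regression of daily water use on micrometeorological
# drivers: solar radiation, wind speed, soil moisture, VPD and reference ET.

#' Vapour pressure deficit
#'
#' `VPD = es(T) * (1 - RH/100)` with the FAO-56 (Tetens) saturation curve.
#'
#' @param temp_c Air temperature, degC.
#' @param rh_pct Relative humidity, percent (0-100).
#' @return VPD, kPa.
#' @export
compute_vpd <- function(temp_c, rh_pct) {
  check_that(all(rh_pct >= 0 & rh_pct <= 100, na.rm = TRUE),
             "relative humidity must be within [0, 100]")
  sat_vapour_pressure(temp_c) * (1 - rh_pct / 100)
}

#' Assemble the daily driver matrix
#'
#' Aggregates half-hourly weather to daily driver values: solar radiation
#' summed to MJ/m2/day, wind and soil moisture averaged, VPD as the daily
#' mean of half-hourly VPD, joined with daily reference ET and the daily
#' response.
#'
#' @param weather Half-hourly weather table.
#' @param soil Half-hourly soil table with `soil_moisture_pct` (optional).
#' @param eto_daily Data frame `date`, `eto_mm`.
#' @param response Data frame `date`, `<response_name>`.
#' @return Data frame with `date`, `solar_radiation`, `wind_speed`,
#'   `soil_moisture`, `vpd`, `eto` and the response column; rows with any
#'   missing cell are dropped.
#' @export
build_driver_matrix <- function(weather, soil = NULL, eto_daily, response) {
  dt_s <- as.numeric(stats::median(diff(as.numeric(weather$timestamp))))
  date <- interval_date(weather$timestamp, dt_s)
  vpd <- compute_vpd(weather$air_temp_c, weather$rh_pct)
  agg <- data.frame(
    date = as.Date(names(tapply(vpd, date, mean))),
    solar_radiation = as.numeric(tapply(weather$solar_wm2 * dt_s / 1e6,
                                        date, sum)),
    wind_speed = as.numeric(tapply(weather$wind_ms, date, mean)),
    vpd = as.numeric(tapply(vpd, date, mean)))
  if (!is.null(soil)) {
    sdate <- interval_date(soil$timestamp, dt_s)
    sm <- data.frame(date = as.Date(names(tapply(soil$soil_moisture_pct,
                                                 sdate, mean))),
                     soil_moisture = as.numeric(
                       tapply(soil$soil_moisture_pct, sdate, mean)))
    agg <- merge(agg, sm, by = "date")
  } else {
    agg$soil_moisture <- NA_real_
  }
  agg <- merge(agg, stats::setNames(eto_daily[, c("date", "eto_mm")],
                                    c("date", "eto")), by = "date")
  agg <- merge(agg, response, by = "date")
  agg[stats::complete.cases(agg), , drop = FALSE]
}

#' Fit the five-driver water-use regression
#'
#' Ordinary least squares with intercept of the response on exactly the
#' five drivers (solar radiation, wind speed, soil moisture, VPD, ETo) --
#' no variable selection, no interactions. Reports the coefficient table
#' (estimate, SE, t, two-sided p) and fit statistics.
#'
#' @param data Driver matrix from [build_driver_matrix()] (columns
#'   `solar_radiation`, `wind_speed`, `soil_moisture`, `vpd`, `eto`).
#' @param response Name of the response column.
#' @return A `driver_fit` list: `coefficients` data frame, `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `df_residual`, `residual_se`, `n`,
#'   `response`, and the underlying `lm` object as `fit`.
#' @export
fit_drivers <- function(data, response) {
  predictors <- c("solar_radiation", "wind_speed", "soil_moisture", "vpd",
                  "eto")
  miss <- setdiff(c(predictors, response), names(data))
  check_that(length(miss) == 0,
             paste("missing columns:", paste(miss, collapse = ", ")))
  data <- data[stats::complete.cases(data[, c(predictors, response)]), ,
               drop = FALSE]
  check_that(nrow(data) >= length(predictors) + 2,
             sprintf("need at least %d complete rows, got %d",
                     length(predictors) + 2, nrow(data)))
  fml <- stats::reformulate(predictors, response)
  mm <- stats::model.matrix(fml, data)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(fml, data = data)
  sm <- suppressWarnings(summary(fit))  # exact fits are valid test inputs
  co <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(co),
                              estimate = co[, 1], std_error = co[, 2],
                              t_value = co[, 3], p_value = co[, 4],
                              row.names = NULL),
    r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(sm$fstatistic[1]),
    df_residual = fit$df.residual, residual_se = sm$sigma,
    n = nrow(data), response = response, fit = fit),
    class = "driver_fit")
}

#' @export
print.driver_fit <- function(x, ...) {
  cat(sprintf("Water-use drivers regression: %s ~ 5 drivers (n = %d)\n",
              x$response, x$n))
  co <- x$coefficients
  co$estimate <- signif(co$estimate, 4)
  co$std_error <- signif(co$std_error, 4)
  co$t_value <- round(co$t_value, 3)
  co$p_value <- format.pval(co$p_value, digits = 3)
  print(co, row.names = FALSE)
  cat(sprintf(
    "Residual SE %.4f on %d df; R2 %.4f, adj. R2 %.4f, F %.2f\n",
    x$residual_se, x$df_residual, x$r_squared, x$adj_r_squared,
    x$f_statistic))
  invisible(x)
}
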