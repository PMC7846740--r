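# Monetary valuation of regional water volumes: basin water tariff and
# irrigated-crop equivalents (area, tonnage, market value, net benefit).

#' Default economic parameters
#'
#' Basin water tariff (payment for ecosystem services, US$ 0.00015/m3) and
#' the two reference crops of the Awash floodplains: cotton (7,000
#' m3/ha/yr, 2.1 t/ha, US$ 500-600/t, benefit-cost ratio 1.49) and sugar
#' cane (15,000 m3/ha/yr, 37 t sugar/ha, US$ 536/t, net benefit-cost ratio
#' 1.12).
#'
#' @return An `econ_params` list.
#' @export
econ_params <- function() {
  structure(list(
    tariff_usd_per_m3 = 0.00015,
    crops = list(
      cotton = list(water_requirement_m3_per_ha = 7000,
                    yield_t_per_ha = 2.1,
                    price_usd_per_t = c(lo = 500, hi = 600),
                    benefit_cost_ratio = 1.49),
      sugarcane = list(water_requirement_m3_per_ha = 15000,
                       yield_t_per_ha = 37,
                       price_usd_per_t = c(lo = 536, hi = 536),
                       benefit_cost_ratio = 1.12))),
    class = "econ_params")
}

# Validate one crop parameter list.
check_crop <- function(crop) {
  check_that(crop$water_requirement_m3_per_ha > 0,
             "crop water requirement must be > 0")
  check_that(crop$yield_t_per_ha > 0, "crop yield must be > 0")
  p <- crop$price_usd_per_t
  check_that(all(p > 0) && p[1] <= p[length(p)],
             "price range must be positive with lo <= hi")
  check_that(crop$benefit_cost_ratio > 0, "benefit-cost ratio must be > 0")
  invisible(TRUE)
}

#' Tariff value of an annual water volume
#'
#' @param volume_m3 Annual volume, m3/yr (>= 0).
#' @param tariff Water tariff, US$/m3.
#' @param signif_digits Significant digits for the rounded report value.
#' @return List with `value_usd` (raw) and `value_usd_rounded`.
#' @export
tariff_value <- function(volume_m3, tariff = 0.00015, signif_digits = 2) {
  check_that(all(volume_m3 >= 0), "volume must be >= 0")
  check_that(tariff > 0, "tariff must be > 0")
  raw <- volume_m3 * tariff
  list(value_usd = raw, value_usd_rounded = signif(raw, signif_digits))
}

#' Crop-production equivalent of an annual water volume
#'
#' The area that could be irrigated (`volume / water requirement`, rounded
#' to the nearest `round_area_to` ha for reporting), its tonnage, market
#' value over the crop's price range, and the net benefit derived from the
#' benefit-cost ratio. Two net-benefit conventions are available:
#' `"one_minus_inverse"` (`market * (1 - 1/BCR)`, the default) and
#' `"bcr_minus_one"` (`market * (BCR - 1)`).
#'
#' @param volume_m3 Annual volume, m3/yr (>= 0).
#' @param crop One crop list from [econ_params()].
#' @param crop_name Label for the output.
#' @param net_formula Net-benefit convention (see above).
#' @param round_area_to Reporting granularity for the area, ha.
#' @param signif_digits Significant digits for rounded monetary values.
#' @return A `crop_equivalent` list with raw and rounded chains.
#' @export
crop_equivalent <- function(volume_m3, crop, crop_name = "crop",
                            net_formula = c("one_minus_inverse",
                                            "bcr_minus_one"),
                            round_area_to = 10000, signif_digits = 2) {
  net_formula <- match.arg(net_formula)
  check_that(all(volume_m3 >= 0), "volume must be >= 0")
  check_crop(crop)
  area_raw <- volume_m3 / crop$water_requirement_m3_per_ha
  area <- round(area_raw / round_area_to) * round_area_to
  tonnage_raw <- area_raw * crop$yield_t_per_ha
  tonnage <- area * crop$yield_t_per_ha
  price <- crop$price_usd_per_t
  market_raw <- tonnage_raw * price
  market <- tonnage * price
  bcr <- crop$benefit_cost_ratio
  factor <- if (net_formula == "one_minus_inverse") 1 - 1 / bcr else bcr - 1
  structure(list(crop = crop_name,
                 area_ha_raw = area_raw, area_ha = area,
                 tonnage_t_raw = tonnage_raw, tonnage_t = tonnage,
                 market_value_usd_raw = market_raw,
                 market_value_usd = signif(market, signif_digits),
                 net_benefit_usd_raw = market_raw * factor,
                 net_benefit_usd = signif(market * factor, signif_digits),
                 net_formula = net_formula,
                 benefit_cost_ratio = bcr),
            class = "crop_equivalent")
}

#' @export
print.crop_equivalent <- function(x, ...) {
  p <- function(v) paste(format(v, big.mark = ","), collapse = " - ")
  cat(sprintf("Crop equivalent (%s, net benefit via %s):\n", x$crop,
              x$net_formula))
  cat(sprintf("  irrigable area %s ha (raw %.0f)\n",
              format(x$area_ha, big.mark = ","), x$area_ha_raw))
  cat(sprintf("  tonnage        %s t\n", p(signif(x$tonnage_t, 3))))
  cat(sprintf("  market value   US$ %s\n", p(x$market_value_usd)))
  cat(sprintf("  net benefit    US$ %s (BCR %.2f)\n", p(x$net_benefit_usd),
              x$benefit_cost_ratio))
  invisible(x)
}

#' Full economic valuation of a water volume
#'
#' Applies [tariff_value()] and [crop_equivalent()] for every configured
#' crop, reporting both net-benefit conventions.
#'
#' @param volume_m3 Annual volume, m3/yr.
#' @param params An [econ_params()] list.
#' @return List with `tariff` and per-crop equivalents (both conventions).
#' @export
economic_valuation <- function(volume_m3, params = econ_params()) {
  crops <- lapply(names(params$crops), function(nm) {
    list(default = crop_equivalent(volume_m3, params$crops[[nm]], nm,
                                   "one_minus_inverse"),
         bcr_minus_one = crop_equivalent(volume_m3, params$crops[[nm]], nm,
                                         "bcr_minus_one"))
  })
  names(crops) <- names(params$crops)
  list(volume_m3 = volume_m3,
       tariff = tariff_value(volume_m3, params$tariff_usd_per_m3),
       crops = crops)
}
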