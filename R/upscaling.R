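# Regional upscaling of stand water use over a fractional-cover raster:
# per-pixel volumes, regional daily/annual totals, invaded area and mean
# annual depth, plus the depth-vs-precipitation share.

#' Fractional-cover raster
#'
#' A georeferenced grid of fractional canopy cover values in [0, 1].
#' Stored as a plain matrix (rows top-down, as in the ESRI ASCII grid
#' format) with cell size and origin.
#'
#' @param values Numeric matrix of cover fractions; `NA` marks nodata.
#' @param cellsize Cell edge length, m (default 15, i.e. 225 m2 pixels).
#' @param xllcorner,yllcorner Lower-left corner coordinates.
#' @param nodata Nodata sentinel used on disk (default -9999).
#' @return A `cover_raster` object.
#' @export
cover_raster <- function(values, cellsize = 15, xllcorner = 0,
                         yllcorner = 0, nodata = -9999) {
  values <- as.matrix(values)
  if (!all(is.na(values))) {
    rng <- range(values, na.rm = TRUE)
    check_that(rng[1] >= 0 && rng[2] <= 1,
               sprintf("cover values must lie in [0, 1]; range is [%g, %g]",
                       rng[1], rng[2]))
  }
  check_that(cellsize > 0, "cellsize must be > 0")
  structure(list(values = values, cellsize = cellsize,
                 xllcorner = xllcorner, yllcorner = yllcorner,
                 nodata = nodata),
            class = "cover_raster")
}

#' @export
print.cover_raster <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "cover_raster: %d x %d cells of %g m (%g m2), %d valid, %d invaded\n",
    nrow(v), ncol(v), x$cellsize, x$cellsize^2, sum(!is.na(v)),
    sum(v > 0, na.rm = TRUE)))
  invisible(x)
}

#' Pixel area of a cover raster, m2
#' @param raster A [cover_raster()].
#' @export
pixel_area <- function(raster) raster$cellsize^2

#' Generate a synthetic fractional-cover raster
#'
#' Invaded pixels are a Bernoulli draw at `invaded_fraction`; their cover
#' values are Beta-distributed in (0, 1] (or a constant, via
#' `constant_value`). Pixel size defaults to the 15 m grid (225 m2).
#'
#' @param rows,cols Grid dimensions (>= 1).
#' @param invaded_fraction Expected share of pixels with cover > 0, in
#'   [0, 1].
#' @param seed Integer seed.
#' @param constant_value If non-`NULL`, all invaded pixels get this cover.
#' @param beta_shape Beta(shape1, shape2) parameters for cover values.
#' @param cellsize Cell edge, m.
#' @return A [cover_raster()].
#' @export
generate_cover_raster <- function(rows, cols, invaded_fraction = 0.3,
                                  seed = 1L, constant_value = NULL,
                                  beta_shape = c(1.1, 4), cellsize = 15) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  check_that(rows >= 1 && cols >= 1, "rows and cols must be >= 1")
  check_that(invaded_fraction >= 0 && invaded_fraction <= 1,
             "invaded_fraction must be in [0, 1]")
  with_seed(seed, {
    n <- rows * cols
    v <- numeric(n)
    inv <- stats::runif(n) < invaded_fraction
    if (any(inv)) {
      v[inv] <- if (!is.null(constant_value)) constant_value
                else stats::rbeta(sum(inv), beta_shape[1], beta_shape[2])
      # Beta draws of exactly 0 would contradict "invaded"; nudge them up
      v[inv] <- pmax(v[inv], 1e-6)
    }
    cover_raster(matrix(v, rows, cols), cellsize = cellsize)
  })
}

#' Water use of one pixel
#'
#' `volume (L/day) = Fc * W (mm/day) * S (m2)`, since 1 mm over 1 m2 is
#' one litre.
#'
#' @param fc Fractional cover in [0, 1].
#' @param wi Stand water use at 100% cover, mm/day (>= 0).
#' @param s Pixel area, m2 (default 225).
#' @return Pixel water use, L/day.
#' @export
pixel_water_use <- function(fc, wi, s = 225) {
  check_that(all(fc >= 0 & fc <= 1, na.rm = TRUE),
             "fractional cover must lie in [0, 1]")
  check_that(all(wi >= 0), "water-use rate must be >= 0")
  fc * wi * s
}

#' Regional water-use totals over a cover raster
#'
#' Sums per-pixel water use over valid pixels: daily volume (m3/day),
#' annual volume (x `annualization` days), invaded area (footprint of
#' pixels with cover > 0; the cover-weighted area is also reported), and
#' the mean annual depth over the invaded area.
#'
#' @param raster A [cover_raster()].
#' @param wi Stand water use at 100% cover, mm/day.
#' @param source Label: `"sapflow"` or `"et"`.
#' @param annualization Days per year used for annual totals (365; no leap
#'   handling).
#' @param per_pixel Also return the per-pixel L/day map as a raster?
#' @return A `regional_estimate` list.
#' @export
regional_totals <- function(raster, wi, source = c("sapflow", "et"),
                            annualization = 365, per_pixel = FALSE) {
  stopifnot(inherits(raster, "cover_raster"))
  source <- match.arg(source)
  check_that(wi >= 0, "water-use rate must be >= 0")
  v <- raster$values
  valid <- !is.na(v)
  check_that(any(valid), "raster has no valid pixels")
  s <- pixel_area(raster)
  daily_l <- sum(pixel_water_use(v[valid], wi, s))
  daily_m3 <- daily_l / 1000
  annual_m3 <- daily_m3 * annualization
  invaded_m2 <- sum(v > 0, na.rm = TRUE) * s
  cover_weighted_m2 <- sum(v[valid]) * s
  depth_mm <- if (invaded_m2 > 0) annual_m3 / invaded_m2 * 1000 else NA_real_
  map <- NULL
  if (per_pixel) {
    pm <- matrix(NA_real_, nrow(v), ncol(v))
    pm[valid] <- pixel_water_use(v[valid], wi, s)
    map <- raster
    map$values <- pm
    class(map) <- "water_use_raster"
  }
  structure(list(source = source, wi_mm_day = wi,
                 daily_volume_m3 = daily_m3, annual_volume_m3 = annual_m3,
                 invaded_area_ha = invaded_m2 / 1e4,
                 cover_weighted_area_ha = cover_weighted_m2 / 1e4,
                 mean_annual_depth_mm = depth_mm,
                 annualization = annualization, per_pixel = map),
            class = "regional_estimate")
}

#' @export
print.regional_estimate <- function(x, ...) {
  cat(sprintf("Regional water use (%s, Wi = %.2f mm/day):\n", x$source,
              x$wi_mm_day))
  cat(sprintf("  daily volume   %.3e m3/day\n", x$daily_volume_m3))
  cat(sprintf("  annual volume  %.3e m3/yr (x%d)\n", x$annual_volume_m3,
              x$annualization))
  cat(sprintf("  invaded area   %.1f ha (cover-weighted %.1f ha)\n",
              x$invaded_area_ha, x$cover_weighted_area_ha))
  cat(sprintf("  mean depth     %.1f mm/yr over the invaded footprint\n",
              x$mean_annual_depth_mm))
  invisible(x)
}

#' Water-use depth as a share of annual precipitation
#'
#' @param estimate A [regional_totals()] result, or a depth in mm/yr.
#' @param annual_precip Annual precipitation, mm (> 0).
#' @return Percentage, `100 * depth / precipitation`.
#' @export
depth_vs_precipitation <- function(estimate, annual_precip) {
  check_that(is.numeric(annual_precip) && annual_precip > 0,
             "annual precipitation must be > 0")
  depth <- if (inherits(estimate, "regional_estimate"))
    estimate$mean_annual_depth_mm else estimate
  100 * depth / annual_precip
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param raster A [cover_raster()] (or per-pixel water-use raster).
#' @param path Output path (.asc).
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(raster, path) {
  v <- raster$values
  header <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.6f", raster$xllcorner),
    sprintf("yllcorner %.6f", raster$yllcorner),
    sprintf("cellsize %.6f", raster$cellsize),
    sprintf("NODATA_value %g", raster$nodata))
  v[is.na(v)] <- raster$nodata
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid as a cover raster
#'
#' Values in 0-100 are autodetected as percent cover and rescaled to
#' [0, 1] (with a message) unless `percent` is set explicitly.
#'
#' @param path Path to the .asc file.
#' @param percent Force percent (`TRUE`) or fraction (`FALSE`)
#'   interpretation; `NA` autodetects.
#' @return A [cover_raster()].
#' @export
read_esri_ascii <- function(path, percent = NA) {
  check_that(file.exists(path), paste("no such file:", path))
  lines <- readLines(path)
  hdr <- list()
  i <- 0
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1
    } else break
  }
  check_that(all(c("ncols", "nrows", "cellsize") %in% names(hdr)),
             "not an ESRI ASCII grid: missing header fields")
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[-seq_len(i)], collapse = "\n"),
               quiet = TRUE)
  check_that(length(vals) == hdr$ncols * hdr$nrows,
             "grid body does not match ncols x nrows")
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == nodata] <- NA
  if (is.na(percent))
    percent <- any(m > 1, na.rm = TRUE) && max(m, na.rm = TRUE) <= 100
  if (isTRUE(percent)) {
    message("cover values look like percentages; rescaling to [0, 1]")
    m <- m / 100
  }
  cover_raster(m, cellsize = hdr$cellsize,
               xllcorner = if (!is.null(hdr$xllcorner)) hdr$xllcorner else 0,
               yllcorner = if (!is.null(hdr$yllcorner)) hdr$yllcorner else 0,
               nodata = nodata)
}
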