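test_that("pixel water use is the cover-rate-area product in litres", {
  expect_equal(pixel_water_use(0, 5, 225), 0)
  expect_equal(pixel_water_use(1, 3.67, 225), 825.75)
  # linear in cover
  expect_equal(pixel_water_use(0.4, 3.67, 225),
               pixel_water_use(0.8, 3.67, 225) / 2)
  expect_error(pixel_water_use(1.3, 3.67), "\\[0, 1\\]")
  expect_error(pixel_water_use(0.5, -1), ">= 0")
})

test_that("regional totals match closed forms and identities", {
  full <- generate_cover_raster(30, 25, 1, seed = 1, constant_value = 1)
  est <- regional_totals(full, wi = 3.4)
  expect_equal(est$daily_volume_m3, 30 * 25 * 3.4 * 225 / 1000)
  expect_equal(est$annual_volume_m3, est$daily_volume_m3 * 365)
  expect_equal(est$invaded_area_ha, 30 * 25 * 225 / 1e4)
  # full cover at 3.4 mm/day annualises to 1241 mm/yr exactly
  expect_equal(est$mean_annual_depth_mm, 1241)

  nodata <- cover_raster(matrix(NA_real_, 3, 3))
  expect_error(regional_totals(nodata, 3), "no valid pixels")

  # partition additivity: totals over row blocks sum to the whole
  r <- generate_cover_raster(40, 40, 0.4, seed = 9)
  top <- cover_raster(r$values[1:20, ], cellsize = r$cellsize)
  bot <- cover_raster(r$values[21:40, ], cellsize = r$cellsize)
  whole <- regional_totals(r, 3.7)
  expect_equal(regional_totals(top, 3.7)$daily_volume_m3 +
                 regional_totals(bot, 3.7)$daily_volume_m3,
               whole$daily_volume_m3)
  # linear in the rate
  expect_equal(regional_totals(r, 7.4)$daily_volume_m3,
               2 * whole$daily_volume_m3)
})

test_that("upscaling equals a brute-force double loop", {
  r <- generate_cover_raster(40, 30, 0.5, seed = 21)
  wi <- 3.42
  est <- regional_totals(r, wi, per_pixel = TRUE)
  acc <- 0
  for (i in seq_len(nrow(r$values)))
    for (j in seq_len(ncol(r$values)))
      acc <- acc + r$values[i, j] * wi * 225
  expect_equal(est$daily_volume_m3, acc / 1000, tolerance = 1e-9)
  expect_equal(sum(est$per_pixel$values, na.rm = TRUE), acc,
               tolerance = 1e-9)
})

test_that("depth vs precipitation is a simple share", {
  expect_equal(depth_vs_precipitation(560, 560), 100)
  expect_equal(depth_vs_precipitation(279, 560), 49.8, tolerance = 0.05)
  expect_equal(depth_vs_precipitation(558, 560),
               2 * depth_vs_precipitation(279, 560))
  expect_error(depth_vs_precipitation(100, 0), "precipitation")
})

test_that("ESRI ASCII grids round-trip and autodetect percent cover", {
  r <- generate_cover_raster(12, 17, 0.5, seed = 2)
  r$values[3, 4] <- NA
  path <- tempfile(fileext = ".asc")
  on.exit(unlink(path), add = TRUE)
  write_esri_ascii(r, path)
  back <- read_esri_ascii(path)
  expect_equal(back$values, r$values, tolerance = 1e-6)
  expect_equal(back$cellsize, 15)

  pct <- cover_raster(matrix(c(0, 0.5, 1, 0.25), 2, 2))
  pct$values <- pct$values * 100   # write a percent-scaled grid
  path2 <- tempfile(fileext = ".asc")
  on.exit(unlink(path2), add = TRUE)
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 15", "NODATA_value -9999",
               "0 100", "50 25"), path2)
  expect_message(back2 <- read_esri_ascii(path2), "percent")
  expect_equal(max(back2$values), 1)
})
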