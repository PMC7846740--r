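test_that("weather generator honours the zero-rain case and its seed", {
  spec0 <- climate_spec(annual_rainfall = 0, seed = 11)
  w0 <- generate_weather(spec0, days = 40)
  expect_true(all(w0$rain_mm == 0))

  spec <- climate_spec(seed = 5)
  expect_identical(generate_weather(spec, days = 10),
                   generate_weather(spec, days = 10))
  expect_error(generate_weather(spec, days = 0), "days")
})

test_that("weather has diurnal solar structure and rain only in season", {
  spec <- climate_spec(seed = 2)
  w <- generate_weather(spec, as.Date("2017-06-15"), days = 60)
  hour <- as.integer(format(w$timestamp - 900, "%H", tz = "UTC"))
  expect_true(all(w$solar_wm2[hour %in% c(0:4, 22, 23)] == 0))
  expect_gt(mean(w$solar_wm2[hour == 12]), mean(w$solar_wm2[hour == 8]))
  mon <- as.integer(format(w$timestamp - 900, "%m", tz = "UTC"))
  expect_true(all(w$rain_mm[!(mon %in% spec$rainy_season_months)] == 0))
  # RH inversely coupled to temperature
  expect_lt(cor(w$air_temp_c, w$rh_pct), -0.5)
  expect_true(all(w$rh_pct >= 0 & w$rh_pct <= 100))
})

test_that("annual rain total matches the model expectation within 3 SDs", {
  spec <- climate_spec(annual_rainfall = 560, seed = 20)
  w <- generate_weather(spec, as.Date("2017-01-01"), days = 365)
  total <- sum(w$rain_mm)
  # days falling in Jul-Sep of a 365-day year starting 1 Jan
  n_rainy <- 31 + 31 + 30
  sd_total <- standwater:::rain_total_sd(spec, n_rainy)
  expect_lt(abs(total - 560), 3 * sd_total)
})

test_that("heat-pulse generator is exact at zero flow and zero noise", {
  probe <- probe_geometry()
  still <- sap_velocity_curve("T0", base_velocity = 0,
                              diurnal_shape = rep(1, 48), noise_sd = 0)
  hp <- generate_heat_pulse_series(still, probe, days = 1)
  expect_equal(hp$v1_C, hp$v2_C)
  expect_error(sap_velocity_curve("T0", base_velocity = -1), "base_velocity")

  # Vh = 18 cm/h with k = 2.5e-3, x = 0.5 means a temperature-rise ratio of e
  flat18 <- sap_velocity_curve("T1", 18, diurnal_shape = rep(1, 48))
  hp18 <- generate_heat_pulse_series(flat18, probe, days = 1)
  expect_equal(hp18$v1_C / hp18$v2_C, rep(exp(1), nrow(hp18)))
})

test_that("turbulence generator hits its targets and is reproducible", {
  spec <- turbulence_spec(target_LE = 0, target_H = 0, seed = 9)
  win <- generate_turbulence(spec)
  expect_lt(abs(cov(win$w, win$T_sonic)), 1e-10)
  expect_lt(abs(cov(win$w, win$h2o_gm3)), 1e-10)
  expect_identical(generate_turbulence(spec), generate_turbulence(spec))
  expect_equal(nrow(win), 10 * 30 * 60)
})

test_that("cover raster matches its invaded fraction and edge cases", {
  empty <- generate_cover_raster(20, 20, invaded_fraction = 0, seed = 1)
  expect_true(all(empty$values == 0))
  full <- generate_cover_raster(15, 12, 1, seed = 1, constant_value = 1)
  est <- regional_totals(full, wi = 3.4)
  expect_equal(est$daily_volume_m3 * 1000, 15 * 12 * 3.4 * 225)
  expect_error(generate_cover_raster(5, 5, 1.2), "invaded_fraction")

  r <- generate_cover_raster(120, 120, 0.35, seed = 4)
  phat <- mean(r$values > 0)
  n <- 120 * 120
  expect_lt(abs(phat - 0.35), 3 * sqrt(0.35 * 0.65 / n))
  expect_true(all(r$values >= 0 & r$values <= 1))
})

test_that("tree inventory is reproducible and recovers its allometry", {
  one <- generate_tree_inventory(1, seed = 3)
  expect_equal(nrow(one), 1)
  expect_identical(generate_tree_inventory(8, seed = 3),
                   generate_tree_inventory(8, seed = 3))
  inv <- generate_tree_inventory(25, area_noise_sd = 0, seed = 6)
  truth <- standwater:::true_allometry_default()
  fit <- fit_allometry(inv$stem_diameter_cm, inv$sapwood_area_cm2)
  expect_lt(abs(fit$intercept - truth$intercept) / abs(truth$intercept),
            1e-6)
  expect_lt(abs(fit$slope - truth$slope) / truth$slope, 1e-6)
  expect_error(generate_tree_inventory(4, diameter_range = c(10, 10)),
               "diameter_range")
})

test_that("soil moisture responds to rainfall as a leaky bucket", {
  spec <- climate_spec(seed = 8)
  w <- generate_weather(spec, as.Date("2017-07-01"), days = 90)
  soil <- generate_soil_series(w, seed = 8)
  date <- as.Date(w$timestamp - 1, tz = "UTC")
  rain_d <- tapply(w$rain_mm, date, sum)
  theta_d <- tapply(soil$soil_moisture_pct, date, mean)
  wet <- rain_d > 5
  expect_gt(mean(diff(theta_d)[wet[-1]]), mean(diff(theta_d)[!wet[-1]]))
})
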