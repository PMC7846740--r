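test_that("despiking replaces only genuine spikes", {
  const <- data.frame(u = rep(2, 600), w = rep(0.1, 600))
  out <- despike(const, cols = c("u", "w"))
  expect_equal(sum(attr(out, "n_replaced")), 0)

  set.seed(1)
  win <- data.frame(w = rnorm(6000, sd = 0.4))
  clean <- despike(win, cols = "w")
  expect_lte(attr(clean, "n_replaced")[["w"]] / 6000, 0.01)
  expect_false(attr(clean, "qc_low_quality"))

  win$w[3000] <- 100 * 0.4
  spiked <- despike(win, cols = "w")
  expect_equal(attr(spiked, "n_replaced")[["w"]],
               attr(clean, "n_replaced")[["w"]] + 1)
})

test_that("double rotation zeroes mean v and w and preserves speed", {
  spec <- turbulence_spec(tilt_deg = c(12, 5), seed = 3,
                          window_minutes = 5)
  win <- generate_turbulence(spec)
  rot <- double_rotation(win)
  expect_lt(abs(mean(rot$v)), 1e-10)
  expect_lt(abs(mean(rot$w)), 1e-10)
  expect_equal(sqrt(rot$u^2 + rot$v^2 + rot$w^2),
               sqrt(win$u^2 + win$v^2 + win$w^2), tolerance = 1e-12)
  ang <- attr(rot, "rotation_angles_deg")
  expect_equal(unname(ang), c(12, 5), tolerance = 1e-8)

  # already-level window: identity up to numerical precision
  level <- generate_turbulence(turbulence_spec(seed = 4,
                                               window_minutes = 5))
  rl <- double_rotation(level)
  expect_equal(rl$u, level$u, tolerance = 1e-12)
  expect_equal(rl$w, level$w, tolerance = 1e-12)

  still <- data.frame(u = rep(0, 10), v = rep(0, 10), w = rep(0, 10))
  expect_error(double_rotation(still), "zero mean wind")
})

test_that("lag correction recovers an injected sensor lag", {
  spec <- turbulence_spec(target_LE = 250, target_H = 120, seed = 6,
                          window_minutes = 10)
  win <- generate_turbulence(spec)
  un <- lag_correct(win, scalars = "h2o_gm3", max_lag_s = 2)
  expect_equal(attr(un, "applied_lag_s")[["h2o_gm3"]], 0)

  # inject a 0.3 s (3-sample) delay of the scalar against w
  lagged <- win
  n <- nrow(win)
  lagged$h2o_gm3 <- c(rep(win$h2o_gm3[1], 3), win$h2o_gm3[1:(n - 3)])
  fixed <- lag_correct(lagged, scalars = "h2o_gm3", max_lag_s = 2)
  expect_equal(attr(fixed, "applied_lag_s")[["h2o_gm3"]], 0.3)
  expect_gt(abs(cov(fixed$w, fixed$h2o_gm3)),
            0.9 * abs(cov(win$w, win$h2o_gm3)))

  # white noise scalar: no credible lag, flagged, unshifted
  noise <- win
  set.seed(2)
  noise$h2o_gm3 <- rnorm(n)
  flagged <- lag_correct(noise, scalars = "h2o_gm3", max_lag_s = 2)
  expect_true(attr(flagged, "qc_low_correlation")[["h2o_gm3"]])
})

test_that("flux computation handles null windows and converts ETa linearly", {
  t0 <- data.frame(u = rep(2, 100), v = 0, w = 0.0,
                   T_sonic = 30, h2o_gm3 = 10)
  fl0 <- ec_fluxes(t0)
  expect_equal(fl0$H_wm2, 0)
  expect_equal(fl0$LE_wm2, 0)
  expect_equal(fl0$ETa_mm, 0)

  # LE of 680.6 W/m2 over a half hour is ~0.5 mm of water at lambda ~2.45
  # MJ/kg; lambda's mild temperature dependence keeps it within 1%
  win <- generate_turbulence(turbulence_spec(target_LE = 680.6,
                                             target_H = 150, seed = 5))
  fl <- ec_fluxes(double_rotation(win))
  expect_equal(fl$LE_wm2, 680.6, tolerance = 1e-6)
  expect_equal(fl$ETa_mm, 0.5, tolerance = 0.01)
  # ETa is exactly linear in LE at fixed temperature
  expect_equal(fl$ETa_mm,
               fl$LE_wm2 * 1800 / (latent_heat(fl$air_temp_c) * 1e6))
})

test_that("pre-aggregated covariances give the same fluxes as raw windows", {
  win <- generate_turbulence(turbulence_spec(target_LE = 310,
                                             target_H = 90, seed = 12))
  fl <- ec_fluxes(win)
  ct <- data.frame(timestamp = as.POSIXct("2017-06-01 12:00:00", tz = "UTC"),
                   cov_wT = cov(win$w, win$T_sonic),
                   cov_wq = cov(win$w, win$h2o_gm3),
                   air_temp_c = mean(win$T_sonic),
                   h2o_gm3 = mean(win$h2o_gm3))
  fl2 <- ec_fluxes_from_cov(ct)
  expect_equal(fl2$H_wm2, fl$H_wm2)
  expect_equal(fl2$LE_wm2, fl$LE_wm2)
})

test_that("soil heat flux adds the storage term above the plates", {
  g <- rep(20, 5)
  const_t <- rep(25, 5)
  expect_equal(as.numeric(soil_heat_flux(g, const_t, 0.2)), g)

  # 1 degC per half hour over 8 cm with Cs = 2.0 MJ/m3/K stores 88.9 W/m2
  warm <- 25 + 0:4
  gs <- soil_heat_flux(g, warm, depth = 0.08, dt_s = 1800, cs = 2.0)
  expect_equal(as.numeric(gs[-1]), rep(20 + 2.0e6 * (1 / 1800) * 0.08, 4),
               tolerance = 1e-12)

  # wetter soil stores more heat
  dry <- soil_heat_flux(g, warm, soil_moisture = 0.10)
  wet <- soil_heat_flux(g, warm, soil_moisture = 0.30)
  expect_true(all(as.numeric(wet[-1]) > as.numeric(dry[-1])))
  expect_gt(attr(wet, "cs_mj_m3_k"), attr(dry, "cs_mj_m3_k"))

  omitted <- soil_heat_flux(g, NULL)
  expect_true(attr(omitted, "storage_omitted"))
  expect_equal(as.numeric(omitted), g)
})

test_that("reference ET vanishes without energy and demand", {
  # no available energy and no wind: both source terms vanish
  expect_equal(penman_monteith_eto(0, 0, 30, 50, 0), 0)
  # saturated air and no available energy
  expect_equal(penman_monteith_eto(0, 0, 30, 100, 2.5), 0)
  expect_error(penman_monteith_eto(1, 0.1, 30, 130, 2), "humidity")
  # typical semi-arid hour is of order a half millimetre
  eto <- penman_monteith_eto(1.8, 0.18, 32, 35, 2.3, 91)
  expect_gt(eto, 0.3); expect_lt(eto, 1.2)
})

test_that("crop coefficient slope behaves on exact and degenerate input", {
  eto <- seq(2, 8, length.out = 20)
  expect_equal(kc_estimate(eto, eto)$slope, 1)
  expect_equal(kc_estimate(rep(0, 20), eto)$slope, 0)
  expect_error(kc_estimate(eto, rep(0, 20)), "zero")
  expect_error(kc_estimate(1:5, 1:5), "at least 10")
})

test_that("synthetic flux series closes the energy balance and hits its Kc", {
  w <- generate_weather(climate_spec(seed = 31), as.Date("2017-02-01"),
                        days = 120)
  fx <- generate_flux_series(w, kc_true = 0.77, noise_sd_daily = 0.2,
                             seed = 31)
  iv <- fx$interval
  expect_true(all(iv$h_wm2 + iv$le_wm2 <= iv$rn_wm2 - iv$g_wm2 + 1e-9))
  # stand ETa mean sits near Kc x mean ETo (paper-scale ~3.7 mm/day)
  expect_equal(mean(fx$daily$eta_mm), 0.77 * mean(fx$daily$eto_mm),
               tolerance = 0.03)
  expect_gt(mean(fx$daily$eta_mm), 2.5)
  expect_lt(mean(fx$daily$eta_mm), 5)
})
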