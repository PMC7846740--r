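test_that("heat-pulse velocity follows the log-ratio law", {
  probe <- probe_geometry(k = 2.5e-3, x = 0.5)
  expect_equal(as.numeric(heat_pulse_velocity(0.5, 0.5, probe)), 0)
  # ratio e gives (k/x) * 1 * 3600 = 18 cm/h
  expect_equal(as.numeric(heat_pulse_velocity(0.4 * exp(1), 0.4, probe)), 18)
  # antisymmetry is exact
  v1 <- runif(50, 0.1, 0.9); v2 <- runif(50, 0.1, 0.9)
  expect_identical(as.numeric(heat_pulse_velocity(v1, v2, probe)),
                   -as.numeric(heat_pulse_velocity(v2, v1, probe)))
  # non-positive rises are invalid, counted, not fatal
  vh <- heat_pulse_velocity(c(0.5, -0.1, 0.4), c(0.5, 0.4, 0), probe)
  expect_equal(attr(vh, "n_invalid"), 2)
  expect_true(is.na(vh[2]) && is.na(vh[3]))
})

test_that("wound correction inflates velocity and validates its table", {
  expect_equal(wound_correct(7.3, coefficients = c(0, 1, 0)), 7.3)
  expect_equal(wound_correct(0, coefficients = c(0, 2.1, -0.02, 0.001)), 0)
  vh <- seq(0.5, 60, by = 0.5)
  for (w in wound_coefficients()$wound_width) {
    vc <- wound_correct(vh, w)
    expect_true(all(vc >= vh), label = sprintf("Vc >= Vh at width %.2f", w))
    expect_true(all(diff(vc) > 0),
                label = sprintf("monotone at width %.2f", w))
  }
  expect_error(wound_correct(10, wound_width = 0.5), "supported widths")
  # reverse flow is corrected antisymmetrically
  expect_equal(wound_correct(-12, 0.20), -wound_correct(12, 0.20))
})

test_that("allometry fit handles exact, degenerate and noiseless inputs", {
  d <- c(5, 10, 15, 20)
  exact <- fit_allometry(d, 2 + 3 * d)
  expect_equal(exact$intercept, 2)
  expect_equal(exact$slope, 3)
  expect_equal(exact$r_squared, 1)
  expect_equal(predict_sapwood_area(exact, 12), 38)
  expect_error(fit_allometry(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_allometry(c(7, 7, 7), c(1, 2, 3)), "identical")
})

test_that("tree sap flow integrates velocity over sapwood annuli", {
  probe1 <- probe_geometry(depths = 1)
  tr <- list(tree_id = "T1", sapwood_area_cm2 = 50)
  t0 <- as.POSIXct("2017-03-01 10:00:00", tz = "UTC")
  vel <- data.frame(timestamp = t0, depth_cm = 1, vc_cmh = 10)
  expect_equal(tree_sap_flow(vel, tr, probe1)$flow_lph, 0.5)
  vel$vc_cmh <- 0
  expect_equal(tree_sap_flow(vel, tr, probe1)$flow_lph, 0)

  # two equal-area annuli (no stem geometry -> equal split): velocity at one
  # depth only gives exactly half the flow of both depths flowing
  probe2 <- probe_geometry(depths = c(0.8, 1.1))
  both <- data.frame(timestamp = t0, depth_cm = c(0.8, 1.1),
                     vc_cmh = c(12, 12))
  onev <- data.frame(timestamp = t0, depth_cm = c(0.8, 1.1),
                     vc_cmh = c(12, 0))
  expect_equal(tree_sap_flow(onev, tr, probe2)$flow_lph,
               tree_sap_flow(both, tr, probe2)$flow_lph / 2)
  # brute-force annulus sum oracle with real geometry
  tree_geo <- list(tree_id = "T2", sapwood_area_cm2 = 60,
                   stem_diameter_cm = 16, bark_depth_cm = 0.5,
                   sapwood_depth_cm = 3)
  ann <- sapwood_annuli(tree_geo, probe2)
  expect_equal(sum(ann), 60)
  v <- c(14, 9)
  velg <- data.frame(timestamp = t0, depth_cm = c(0.8, 1.1), vc_cmh = v)
  expect_equal(tree_sap_flow(velg, tree_geo, probe2)$flow_lph,
               sum(v * ann) * 1e-3)
  # all depths invalid -> gap
  velna <- data.frame(timestamp = t0, depth_cm = c(0.8, 1.1),
                      vc_cmh = c(NA, NA))
  expect_true(is.na(tree_sap_flow(velna, tree_geo, probe2)$flow_lph))
})

test_that("daily aggregation sums, gap-fills and applies QC", {
  tr <- list(tree_id = "T1", canopy_area_m2 = 2)
  d <- daily_aggregate(constant_flow(0.5, days = 1), tr)
  expect_equal(d$volume_l, 12)
  expect_equal(d$depth_mm, 6)
  expect_equal(d$qc, 1)

  # interior gaps up to 2 h in a constant series are interpolated exactly:
  # the gap-filled day totals the same as the complete day
  flow <- constant_flow(0.5, days = 1)
  holey <- flow[-c(21:24, 31:34), ]
  dh <- daily_aggregate(holey, tr)
  expect_equal(dh$volume_l, d$volume_l)
  expect_equal(dh$qc, 1)

  # a 6-h hole exceeds the 2-h gap limit: day dropped and counted
  gappy <- flow[-(20:31), ]
  dg <- daily_aggregate(gappy, tr)
  expect_equal(nrow(dg), 0)
  expect_equal(attr(dg, "n_dropped_days"), 1)

  expect_equal(nrow(daily_aggregate(constant_flow(1, 1)[0, ], tr)), 0)
  # volumes are additive over disjoint day partitions
  two <- daily_aggregate(constant_flow(0.25, days = 2), tr)
  expect_equal(sum(two$volume_l), 12)
  expect_equal(two$volume_l, c(6, 6))
})

test_that("habitat summary validates labels and flags single trees", {
  fix <- daily_from_means(list(dryland = 4.2), days = 5)
  s <- habitat_summary(fix$daily, fix$trees)
  expect_equal(s$mean_l_day[s$group == "dryland"], 4.2)
  expect_equal(s$sd_l_day[s$group == "dryland"], 0)
  expect_false(s$sd_defined[s$group == "dryland"])
  bad <- fix$trees; bad$habitat <- "savanna"
  expect_error(habitat_summary(fix$daily, bad), "unknown habitat")
})

test_that("seasonal summary splits windows and recovers seasonal ratios", {
  fix <- daily_from_means(table1_tree_means(), days = 400)
  ss <- seasonal_summary(fix$daily, fix$trees)
  dry <- ss[ss$season == "dry" & ss$group == "all", ]
  rainy <- ss[ss$season == "rainy" & ss$group == "all", ]
  expect_equal(dry$mean_l_day, rainy$mean_l_day)  # constant series

  jan <- fix$daily[as.integer(format(fix$daily$date, "%m")) == 1, ]
  empty_rainy <- seasonal_summary(jan, fix$trees)
  expect_true(empty_rainy$empty[empty_rainy$season == "rainy"][1])

  # generator round-trip: dry-season multiplier 1.25 on sap velocity shows
  # up as the dry/rainy ratio of daily means
  probe <- probe_geometry()
  seas <- rep(1, 12); seas[1:3] <- 1.25
  curve <- sap_velocity_curve("T1", 3, seasonal_multiplier = seas,
                              noise_sd = 0.4)
  hp <- generate_heat_pulse_series(curve, probe, as.Date("2017-01-01"),
                                   days = 270, seed = 2)
  vt <- sap_velocity_table(hp, probe, wound = FALSE)
  tr <- data.frame(tree_id = "T1", habitat = "dryland",
                   sapwood_area_cm2 = 40, canopy_area_m2 = 2,
                   stem_diameter_cm = 14, bark_depth_cm = 0.5,
                   sapwood_depth_cm = 3)
  daily <- daily_aggregate(tree_sap_flow(vt, tr, probe), tr)
  ss2 <- seasonal_summary(daily, tr)
  ratio <- ss2$mean_l_day[ss2$season == "dry" & ss2$group == "all"] /
    ss2$mean_l_day[ss2$season == "rainy" & ss2$group == "all"]
  expect_equal(ratio, 1.25, tolerance = 0.05)
})

test_that("stand transpiration weights size classes correctly", {
  one <- data.frame(proportion = 1, representative_flow_l_day = 7)
  expect_equal(as.numeric(stand_transpiration(one, canopy_area = 2)), 3.5)
  two <- data.frame(proportion = c(0.5, 0.5),
                    representative_flow_l_day = c(4, 8))
  expect_equal(as.numeric(stand_transpiration(two, canopy_area = 2)), 3.0)
  # density mode: trees/m2 turns L/tree/day into mm/day of ground area
  expect_equal(as.numeric(stand_transpiration(two, mode = "density",
                                              stand_density = 0.4)), 2.4)
  bad <- data.frame(proportion = c(0.6, 0.5),
                    representative_flow_l_day = c(4, 8))
  expect_error(stand_transpiration(bad), "sum to 1")
})

test_that("size-class table assigns representative flows per class", {
  fix <- daily_from_means(table1_tree_means(), days = 5)
  ct <- size_class_table(fix$daily, fix$trees, breaks = c(0, 15, 25, 40))
  expect_equal(sum(ct$proportion), 1)
  expect_equal(nrow(ct), 3)
  mm <- stand_transpiration(ct, canopy_area = 2)
  expect_true(as.numeric(mm) > 0)
  reg <- size_class_table(fix$daily, fix$trees, breaks = c(0, 15, 25, 40),
                          mode = "regression")
  expect_equal(nrow(reg), 3)
})
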