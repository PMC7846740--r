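# Shared fixtures, built in code at test time.

# Published per-tree mean daily water use (L/tree/day) for the twelve
# instrumented trees, by habitat.
table1_tree_means <- function() {
  list(floodplain = c(2.6, 6.2, 11.4, 1.9, 4.1, 4.5),
       dryland = c(2.4, 5.1, 19.2, 6.5, 9.5, 8.1))
}

# Daily-flow table and matching inventory in which each tree's period mean
# equals a prescribed value exactly (constant daily volumes).
daily_from_means <- function(means, days = 10, canopy_area = 2) {
  ids <- sprintf("T%02d", seq_along(unlist(means)))
  habitat <- rep(names(means), lengths(means))
  vol <- unlist(means, use.names = FALSE)
  daily <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(tree_id = ids[i],
               date = as.Date("2017-01-01") + seq_len(days) - 1,
               volume_l = vol[i], depth_mm = vol[i] / canopy_area, qc = 1)
  }))
  trees <- data.frame(tree_id = ids, site = "S1", habitat = habitat,
                      stem_diameter_cm = seq(8, 30,
                                             length.out = length(ids)),
                      bark_depth_cm = 0.5, sapwood_depth_cm = 3,
                      sapwood_area_cm2 = 40, canopy_area_m2 = canopy_area)
  list(daily = daily, trees = trees)
}

# Regular half-hourly flow series at a constant rate, interval-ending.
constant_flow <- function(lph, days = 1, start = "2017-03-01") {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  data.frame(timestamp = t0 + seq_len(48 * days) * 1800, flow_lph = lph)
}
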