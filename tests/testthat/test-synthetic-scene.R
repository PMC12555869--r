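test_that("volumes are bit-identical under the same seed and config", {
  cm <- compact_lattice_map()
  cfg <- scene_config(seed = 9, precip_cells = list(count = 1),
                      bird_targets = list(count = 50))
  stamp <- as.POSIXct("2021-07-02 11:00", tz = "UTC")
  v1 <- simulate_scan_volume(cfg, cm$site, NULL, stamp)
  v2 <- simulate_scan_volume(cfg, cm$site, NULL, stamp)
  expect_identical(v1$sweeps, v2$sweeps)
  # different timestamps draw different fields
  v3 <- simulate_scan_volume(cfg, cm$site, NULL, stamp + 3600)
  expect_false(identical(v1$sweeps[[1]]$Z, v3$sweeps[[1]]$Z))
})

test_that("zero insect density leaves no arthropod gates downstream", {
  cm <- compact_lattice_map()
  cfg <- scene_config(seed = 2, insect_layer = list(base_density = 0,
                                                    vertical_slope = 0),
                      diel_curve = NULL, season_envelope = NULL)
  vol <- simulate_scan_volume(cfg, cm$site, NULL,
                              as.POSIXct("2021-07-01 11:00", tz = "UTC"))
  fv <- filter_volume(vol)
  expect_equal(unname(attr(fv, "label_counts")[["arthropod"]]), 0)
})

test_that("diel and seasonal multipliers shape activity as configured", {
  cfg <- scene_config()
  h <- seq(0, 23.75, by = 0.25)
  m <- diel_multiplier(cfg, h)
  # two dominant peaks at the configured centres
  expect_equal(h[which.max(m)], 11)
  night <- m[h < 5]
  expect_true(all(night < 0.05))
  # seasonal envelope exactly zero in January, positive mid-year
  expect_equal(season_multiplier(cfg, c(1, 15, 31)), rep(0, 3))
  expect_gt(season_multiplier(cfg, 200), 0.99)
  # January scan contains no arthropod-classified gates
  cm <- compact_lattice_map()
  vol <- simulate_scan_volume(cfg, cm$site, NULL,
                              as.POSIXct("2021-01-15 11:00", tz = "UTC"))
  fv <- filter_volume(vol)
  expect_equal(unname(attr(fv, "label_counts")[["arthropod"]]), 0)
})

test_that("true per-band densities strictly decrease with height", {
  cm <- compact_lattice_map()
  vol <- simulate_scan_volume(scene_config(seed = 1, diel_curve = NULL,
                                           season_envelope = NULL),
                              cm$site, cm$lattice,
                              as.POSIXct("2021-07-01 11:00", tz = "UTC"))
  truth <- attr(vol, "truth")
  one <- truth[truth$cell_id == truth$cell_id[1], ]
  one <- one[order(one$band_lower), ]
  expect_true(all(diff(one$true_density) < 0))
})

test_that("class distributions separate by construction on sampled gates", {
  cfg <- scene_config(seed = 31)
  n <- 1e5
  ins <- sample_gates(n, cfg, "insect", seed = 31)
  pre <- sample_gates(n, cfg, "precipitation", seed = 32)
  dr_ins <- depolarization_ratio(ins$zdr, ins$rho_hv)
  dr_pre <- depolarization_ratio(pre$zdr, pre$rho_hv)
  expect_gt(mean(dr_pre < -12.5), 0.99)
  expect_gt(mean(dr_ins >= -12.5 & ins$zdr > 3), 0.99)
})

test_that("covariate rasters are smooth, in range, with land cover <= 100%", {
  cov <- generate_covariate_rasters(scene_config(seed = 5))
  r <- cov$rasters
  expect_setequal(names(r), c("tmax", "rain", "wind", "alan", "elevation",
                              "arable", "woodland", "grassland", "urban"))
  expect_true(all(r$alan$values >= 0 & r$alan$values <= 63))
  lc <- r$arable$values + r$woodland$values + r$grassland$values +
    r$urban$values
  expect_true(all(lc <= 100 + 1e-9))
  expect_true(all(r$arable$values >= 0 & r$arable$values <= 100))
  # smoothness: neighbouring cells differ far less than the field range
  v <- r$tmax$values
  expect_lt(max(abs(diff(v))), diff(range(v)) / 4)
  # determinism
  cov2 <- generate_covariate_rasters(scene_config(seed = 5))
  expect_identical(cov2$rasters$tmax$values, v)
})

test_that("trap counts couple exactly to near-ground truth when noiseless", {
  cm <- compact_lattice_map()
  st <- simulate_study(noiseless_config(seed = 4), cm$site, cm$lattice,
                       as.Date("2021-07-01") + 0:2, hours = c(11, 12),
                       scan_interval_min = 60, mapping = cm$mapping)
  trap <- simulate_trap_counts(st$truth, scaling = 1, noise_sd_log = 0)
  expect_equal(nrow(trap), 3)
  low <- st$truth[st$truth$band_lower == 100, ]
  daily <- tapply(low$true_density, as.Date(low$timestamp, tz = "UTC"), mean)
  expect_equal(trap$count, as.numeric(daily), tolerance = 1e-12)
  # rain flags mark exactly the requested days
  trap2 <- simulate_trap_counts(st$truth, rain_days = as.Date("2021-07-02"))
  expect_equal(sum(trap2$rain), 1)
  expect_equal(nrow(trap2[!trap2$rain, ]), 2)
})

test_that("simulate_study rejects empty dates and stacks valid bands", {
  cm <- compact_lattice_map()
  expect_error(simulate_study(scene_config(), cm$site, cm$lattice,
                              as.Date(character()), mapping = cm$mapping),
               "empty date range")
  st <- simulate_study(noiseless_config(seed = 6), cm$site, cm$lattice,
                       as.Date("2021-07-01"), hours = c(11, 12),
                       scan_interval_min = 30, mapping = cm$mapping)
  expect_true(all(st$profiles_filtered$band_valid))
  expect_false(anyDuplicated(st$profiles_filtered[, c("cell_id",
    "band_lower", "timestamp")]) > 0)
})

test_that("volume CSV serialization round-trips moments and geometry", {
  cm <- compact_lattice_map()
  vol <- simulate_scan_volume(scene_config(seed = 12), cm$site, NULL,
                              as.POSIXct("2021-07-01 11:00", tz = "UTC"))
  path <- tempfile(fileext = ".csv")
  write_volume_csv(vol, path)
  back <- read_volume_csv(path)
  expect_equal(back$timestamp, vol$timestamp)
  expect_equal(back$site$elevation_angles, cm$site$elevation_angles)
  for (k in seq_along(vol$sweeps)) {
    expect_equal(back$sweeps[[k]]$Z, vol$sweeps[[k]]$Z, tolerance = 1e-12)
    expect_equal(back$sweeps[[k]]$RHOHV, vol$sweeps[[k]]$RHOHV,
                 tolerance = 1e-12)
  }
})
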