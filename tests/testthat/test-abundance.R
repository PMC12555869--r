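test_that("beta matches the Rayleigh conversion constant", {
  expect_equal(compute_beta(5.0, 0.93), 26.58, tolerance = 1e-3)
  expect_equal(compute_beta(10.7, 0.93), 13.37, tolerance = 1e-3)
  expect_equal(compute_beta(5.0, 1.0), 26.90, tolerance = 1e-3)
  # decreasing in wavelength
  wl <- seq(3, 11, by = 0.5)
  expect_true(all(diff(compute_beta(wl)) < 0))
  expect_error(compute_beta(-1), "positive")
})

test_that("sigma is mandatory and beta may be computed from wavelength", {
  expect_error(radar_constants(), "sigma")
  expect_error(radar_constants(sigma = -2), "sigma")
  ct <- radar_constants(sigma = 1)
  expect_equal(ct$beta, 26.58)
  expect_equal(ct$v_h, pi * 2.5^2 * 0.2, tolerance = 1e-12)
  ct2 <- radar_constants(sigma = 1, beta = NULL, wavelength = 5.0)
  expect_equal(ct2$beta, 26.58, tolerance = 1e-3)
  expect_match(ct2$beta_source, "wavelength")
})

test_that("band conversion follows eta = Z + beta and density = eta_lin/sigma", {
  ct <- radar_constants(sigma = 1)
  out <- band_abundance(0, ct)
  expect_equal(out$eta_db, 26.58)
  expect_equal(out$density, 10^2.658, tolerance = 1e-12)
  expect_equal(out$total_count, 10^2.658 * pi * 6.25 * 0.2, tolerance = 1e-9)
  # eta_lin = sigma gives density 1
  ct5 <- radar_constants(sigma = 455)
  expect_equal(band_abundance(10 * log10(455) - 26.58, ct5)$density, 1,
               tolerance = 1e-12)
  # density is independent of the band volume
  ct_a <- radar_constants(sigma = 2, cvp_radius_km = 2.5, band_depth_km = 0.2)
  ct_b <- radar_constants(sigma = 2, cvp_radius_km = 5, band_depth_km = 0.4)
  expect_equal(band_abundance(17, ct_a)$density, band_abundance(17, ct_b)$density)
  # conversion round trip Z -> density -> Z is the identity
  z <- seq(-15, 40, by = 2.5)
  d <- band_abundance(z, ct)$density
  expect_equal(10 * log10(d * ct$sigma) - ct$beta, z, tolerance = 1e-9)
})

test_that("noiseless scene densities match painted truth end to end", {
  cm <- compact_lattice_map()
  cfg <- noiseless_config(seed = 8, sigma_true = 0.5)
  vol <- simulate_scan_volume(cfg, cm$site, cm$lattice,
                              as.POSIXct("2021-07-01 11:00", tz = "UTC"))
  p <- build_profile(filter_volume(vol), cm$mapping)
  ct <- radar_constants(sigma = 0.5, beta = cfg$beta)
  valid <- p[p$band_valid, ]
  est <- band_abundance(valid$mean_z, ct)
  truth <- attr(vol, "truth")
  tru <- truth$true_density[match(paste(valid$cell_id, valid$band_lower),
                                  paste(truth$cell_id, truth$band_lower))]
  expect_true(all(abs(est$density - tru) / tru <= 1e-6))
})

test_that("vertical gradient recovers linear profiles and rejects < 3 bands", {
  bands <- height_band_edges()
  # exact linear profile: slope recovered exactly, R^2 = 1
  ab <- 9e5 - 1e5 * (bands - 100) / 200
  g <- suppressWarnings(vertical_gradient(bands, ab))
  expect_equal(g$slope, -1e5, tolerance = 1e-9)
  expect_equal(g$adj_r2, 1, tolerance = 1e-9)
  # constant profile: slope 0
  g0 <- suppressWarnings(vertical_gradient(bands, rep(5, 10)))
  expect_equal(g0$slope, 0, tolerance = 1e-9)
  expect_error(vertical_gradient(c(100, 300), c(1, 2)), "3")
  # noisy linear truth: slope within 2 SE
  set.seed(14)
  noisy <- rep(ab, each = 30) + rnorm(300, 0, 5e4)
  gn <- vertical_gradient(rep(bands, each = 30), noisy)
  expect_lt(abs(gn$slope - (-1e5)), 2 * gn$se)
})

test_that("regional extrapolation is the density-area-depth product", {
  expect_equal(extrapolate_region(1, 10, 0.2), 2)
  expect_equal(extrapolate_region(4.61e7, 35728, 0.2) / 2,
               extrapolate_region(4.61e7, 35728 / 2, 0.2))
  # conservation: uniform scene total equals truth summed over band volumes
  cm <- compact_lattice_map()
  cfg <- noiseless_config(seed = 3)
  vol <- simulate_scan_volume(cfg, cm$site, cm$lattice,
                              as.POSIXct("2021-07-01 11:00", tz = "UTC"))
  truth <- attr(vol, "truth")
  b500 <- truth[truth$band_lower == 500, ]
  ct <- radar_constants(sigma = 1)
  total_truth <- sum(b500$true_density * ct$v_h)
  total_extrap <- extrapolate_region(mean(b500$true_density),
                                     nrow(b500) * pi * 2.5^2, 0.2)
  expect_equal(total_extrap, total_truth, tolerance = 1e-9)
})

test_that("standardized OLS slope equals Pearson r; rain days drop out", {
  set.seed(15)
  n <- 200
  x <- rlnorm(n); y <- 2 * x + rlnorm(n)
  dates <- as.Date("2021-05-01") + seq_len(n) - 1
  trap <- data.frame(date = dates, count = x)
  est <- data.frame(date = dates, band_lower = 100, density = y)
  fit <- trap_validation_ols(trap, est)
  expect_equal(fit$slope, cor(x, y), tolerance = 1e-12)
  # identical series: slope 1, R^2 = 1
  est2 <- data.frame(date = dates, band_lower = 100, density = x)
  fit2 <- suppressWarnings(trap_validation_ols(trap, est2))
  expect_equal(fit2$slope, 1, tolerance = 1e-12)
  expect_equal(fit2$adj_r2, 1, tolerance = 1e-12)
  # independent noise: slope ~ 0, not significant
  est3 <- data.frame(date = dates, band_lower = 100,
                     density = rlnorm(n))
  fit3 <- trap_validation_ols(trap, est3)
  expect_lt(abs(fit3$slope), 0.15)
  expect_gt(fit3$p, 0.05)
  # rain-day exclusion leaves n_total - n_rain rows
  rain <- dates[1:9]
  fit4 <- suppressWarnings(trap_validation_ols(trap, est2, rain_days = rain))
  expect_equal(fit4$n_days, n - 9)
  expect_error(trap_validation_ols(trap[1:5, ], est2), "overlapping")
})

test_that("validation slopes decrease with height on the shared-signal series", {
  sim <- simulate_validation_series(n_days = 2000, seed = 16)
  fit <- trap_validation_ols(sim$trap[!sim$trap$rain, ], sim$estimates)
  expect_equal(fit$band_lower, height_band_edges())
  expect_true(all(diff(fit$slope) < 0))
  # strongest coupling at the lowest band
  expect_gt(fit$slope[1], 0.6)
  expect_lt(fit$slope[10], 0.2)
})

test_that("abundance estimates join selections to valid profile bands", {
  cm <- compact_lattice_map()
  st <- simulate_study(scene_config(seed = 23), cm$site, cm$lattice,
                       as.Date("2021-07-01"), hours = c(8, 14),
                       scan_interval_min = 60, mapping = cm$mapping)
  sel <- select_scan_per_window(st$profiles_raw,
                                preset_windows()$diel[1, ], band = 500)
  ct <- radar_constants(sigma = 1)
  est <- abundance_estimates(st$profiles_filtered, sel, ct)
  expect_true(all(est$window == "diurnal"))
  expect_true(all(est$density >= 0))
  expect_true(all(est$total_count == est$density * ct$v_h))
  # one selected scan contributes at most one row per cell and band
  expect_equal(anyDuplicated(est[, c("cell_id", "date", "window",
                                     "band_lower")]), 0L)
  # empty selection gives an empty, well-formed table
  est0 <- abundance_estimates(st$profiles_filtered, sel[0, ], ct)
  expect_equal(nrow(est0), 0)
})
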