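# the criterion-scale recovery table (n ~ 2000) is cached across tests
recovery_setup <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lat <- default_lattice()
      tab <- simulate_trend_table(lat, seed = 101)
      spec <- trend_spec(list(
        term_smooth("tmax", 8), term_smooth("rain", 8),
        term_smooth2d(c("x", "y"), 30), term_ti(c("year", "y"), 5),
        term_smooth("year", 5)), name = "recovery")
      fit <- suppressWarnings(fit_trend_gam(spec, tab, response = "density"))
      cache <<- list(lattice = lat, table = tab, fit = fit)
    }
    cache
  }
})

test_that("rho estimation recovers AR(1) truth and rejects degenerate input", {
  set.seed(31)
  # white noise: |rho| small
  wn <- rnorm(5000)
  expect_lt(abs(estimate_rho(wn)), 0.05)
  # AR(1) truth 0.6 recovered
  x <- as.numeric(arima.sim(list(ar = 0.6), 5000))
  expect_true(estimate_rho(x) > 0.55 && estimate_rho(x) < 0.65)
  # invariance to residual scaling
  expect_equal(estimate_rho(x), estimate_rho(100 * x), tolerance = 1e-12)
  # pooled across series: per-series structure respected
  ser <- rep(1:50, each = 100)
  xs <- unlist(lapply(1:50, function(i)
    as.numeric(arima.sim(list(ar = 0.6), 100))))
  expect_lt(abs(estimate_rho(xs, ser) - 0.6), 0.05)
  expect_error(estimate_rho(rep(1, 10)), "zero variance")
})

test_that("known smooth effects, rho and the change map are recovered", {
  rs <- recovery_setup()
  fit <- rs$fit
  tab <- rs$table
  # rho within +-0.1 of the simulated 0.6
  expect_lt(abs(fit$rho_estimated - 0.6), 0.1)
  # effect-curve correlations >= 0.9 per retained term
  eff <- attr(tab, "effects")
  tm <- predict(fit$fit, type = "terms")
  cn <- colnames(tm)
  expect_gt(cor(tm[, grep("tmax", cn)], eff$tmax(fit$data$tmax)), 0.9)
  expect_gt(cor(tm[, grep("rain", cn)], eff$rain(fit$data$rain)), 0.9)
  # change map reproduces the true north-negative/south-positive pattern
  tr <- annual_trend(fit)
  truth_change <- fit$data$trend_true[match(tr$change$cell_id,
                                            fit$data$cell_id)]
  expect_gt(cor(tr$change$change, truth_change), 0.8)
  strong <- abs(truth_change) > median(abs(truth_change))
  expect_gt(mean(sign(tr$change$change[strong]) ==
                   sign(truth_change[strong])), 0.9)
})

test_that("residual correlogram is clean for the correct model and flags a missing spatial term", {
  rs <- recovery_setup()
  rc <- residual_cell_means(rs$fit, rs$lattice)
  mi <- morans_i_correlogram(rc$resid, rc$x, rc$y, alternative = "greater")
  expect_gt(mi$p[1], 0.05)
  # omit f(x, y): strong positive first-bin autocorrelation
  spec_ns <- trend_spec(list(term_smooth("tmax", 8), term_smooth("rain", 8),
                             term_smooth("year", 5)), name = "nospat")
  fit_ns <- suppressWarnings(fit_trend_gam(spec_ns, rs$table,
                                           response = "density"))
  rc_ns <- residual_cell_means(fit_ns, rs$lattice)
  mi_ns <- morans_i_correlogram(rc_ns$resid, rc_ns$x, rc_ns$y,
                                alternative = "greater")
  expect_gt(mi_ns$observed[1], 0)
  expect_lte(mi_ns$p[1], 0.01)
})

test_that("Moran's I matches analytic expectation, an independent oracle, and sign constructions", {
  set.seed(32)
  n <- 500
  x <- runif(n, 0, 60); y <- runif(n, 0, 60)
  z <- rnorm(n)
  mi <- morans_i_correlogram(z, x, y, breaks = c(0, 10, 20, 30))
  # iid: observed close to -1/(n-1), not significant
  expect_equal(mi$expected, rep(-1 / (n - 1), 3))
  expect_true(all(abs(mi$observed - mi$expected) < 0.05))
  expect_true(all(mi$p > 0.05))
  # cross-check against ape::Moran.I (which row-normalizes weights) on a
  # complete graph, where row sums are equal and the two conventions agree
  skip_if_not_installed("ape")
  w <- matrix(1, n, n); diag(w) <- 0
  mi_all <- morans_i_correlogram(z, x, y, breaks = c(0, 1e6))
  expect_equal(mi_all$observed[1],
               suppressWarnings(ape::Moran.I(z, w))$observed,
               tolerance = 1e-9)
  # smooth spatial field: first-bin positive, significant
  zs <- sin(x / 10) + cos(y / 10) + rnorm(n, 0, 0.2)
  mis <- morans_i_correlogram(zs, x, y, breaks = c(0, 10))
  expect_gt(mis$observed[1], 0)
  expect_lte(mis$p[1], 0.01)
  # checkerboard on a grid with nearest-neighbour band: negative I
  g <- expand.grid(x = 1:10, y = 1:10)
  zc <- (-1)^(g$x + g$y)
  mic <- morans_i_correlogram(zc, g$x, g$y, breaks = c(0, 1))
  expect_lt(mic$observed[1], 0)
  # empty bin flagged
  mie <- morans_i_correlogram(z, x, y, breaks = c(1000, 2000))
  expect_true(mie$flagged[1])
})

test_that("pure linear effect is recovered with other terms shrunk to zero", {
  lat <- default_lattice()
  set.seed(33)
  ret <- retained_cells(lat)
  tab <- data.frame(cell_id = factor(rep(ret$cell_id, each = 8)),
                    x = rep(ret$easting_km, each = 8),
                    y = rep(ret$northing_km, each = 8),
                    year = rep(2014:2021, times = nrow(ret)))
  tab$date <- as.Date(sprintf("%d-06-01", tab$year))
  tab$tmax <- rnorm(nrow(tab), 18, 4)
  tab$rain <- rexp(nrow(tab), 0.2)
  # near-noiseless linear truth (tiny jitter keeps REML well defined)
  tab$density <- 10^(2 + 0.05 * tab$tmax + rnorm(nrow(tab), 0, 1e-3)) - 1
  spec <- trend_spec(list(term_smooth("tmax", 8), term_smooth("rain", 8),
                          term_smooth("year", 5)), name = "lin")
  fit <- suppressWarnings(fit_trend_gam(spec, tab, response = "density",
                                        rho = 0))
  mu <- predict(fit$fit)
  expect_lt(sqrt(mean((mu - (2 + 0.05 * fit$data$tmax))^2)), 1e-3)
  # the irrelevant terms shrink to ~0 EDF
  expect_lt(sum(fit$edf[grep("rain|year", names(fit$edf))]), 0.5)
  expect_gt(fit$deviance_explained, 0.999)
})

test_that("null data yields near-zero deviance explained; intercept-only is exactly zero", {
  lat <- default_lattice()
  set.seed(34)
  tab <- simulate_trend_table(lat, effects = list(tmax = function(x) 0 * x,
                                                  rain = function(x) 0 * x),
                              spatial = function(x, y) 0 * x,
                              trend = function(n) 0 * n, rho = 0,
                              noise_sd = 0.3, seed = 34)
  spec <- trend_spec(list(term_smooth("tmax", 8), term_smooth("rain", 8),
                          term_smooth("year", 5)), name = "null")
  fit <- suppressWarnings(fit_trend_gam(spec, tab, response = "density",
                                        rho = 0))
  expect_lt(fit$deviance_explained, 0.05)
  fit0 <- suppressWarnings(fit_trend_gam(trend_spec(list(), name = "int"),
                                         tab, response = "density", rho = 0))
  expect_equal(fit0$deviance_explained, 0, tolerance = 1e-12)
})

test_that("model selection ranks the generating structure first", {
  lat <- default_lattice()
  # truth has spatial structure + tmax effect; candidates form a ladder
  specs <- list(
    trend_spec(list(term_smooth("year", 5)), name = "year_only"),
    trend_spec(list(term_smooth("year", 5), term_smooth2d(c("x", "y"), 30)),
               name = "spatial"),
    trend_spec(list(term_smooth("year", 5), term_smooth2d(c("x", "y"), 30),
                    term_smooth("tmax", 8)), name = "spatial_tmax"))
  wins <- 0L
  for (s in 1:5) {
    tab <- simulate_trend_table(lat, trend = function(n) 0 * n, rho = 0,
                                effects = list(
                                  tmax = function(x) 0.4 * tanh((x - 18) / 4),
                                  rain = function(x) 0 * x),
                                seed = 200 + s)
    sel <- select_best_model(specs, tab, response = "density", rho = 0)
    if (sel$ranking$name[1] == "spatial_tmax") wins <- wins + 1L
  }
  expect_gte(wins, 4L)
  # deviance explained is non-decreasing along the nested ladder
  tab <- simulate_trend_table(lat, seed = 299, rho = 0)
  sel <- select_best_model(specs, tab, response = "density", rho = 0)
  dev <- sel$ranking$dev_expl[match(c("year_only", "spatial",
                                      "spatial_tmax"), sel$ranking$name)]
  expect_true(all(diff(dev) >= -1e-9))
  # duplicate candidates tie with stable index ordering
  dup <- select_best_model(list(specs[[1]],
                                trend_spec(list(term_smooth("year", 5)),
                                           name = "year_copy")),
                           tab, response = "density", rho = 0)
  expect_equal(diff(dup$ranking$aic), 0, tolerance = 1e-8)
  expect_equal(dup$ranking$name, c("year_only", "year_copy"))
})

test_that("candidate ladder nests the full model and adapts to the table", {
  ladder <- candidate_ladder()
  expect_length(ladder, 7)
  nterms <- vapply(ladder, function(s) length(s$terms), 0L)
  expect_true(all(diff(nterms) > 0))
  full_vars <- ladder[[6]]$vars
  expect_true(all(c("year", "x", "y", "radar", "month", "cell_id", "tmax",
                    "rain", "wind", "arable", "woodland", "grassland",
                    "urban", "alan", "elevation") %in% full_vars))
})

test_that("prediction maps evaluate the fit with SEs and extrapolation flags", {
  rs <- recovery_setup()
  fit <- rs$fit
  # training-point predictions equal fitted values
  mu <- predict(fit$fit)
  expect_equal(as.numeric(predict(fit$fit, newdata = fit$data)),
               as.numeric(mu), tolerance = 1e-9)
  # constant-covariate rasters: spatial variation only from f(x, y) + trend
  const <- list(tmax = constant_raster(18, 30, 2, "tmax"),
                rain = constant_raster(5, 30, 2, "rain"))
  maps <- predict_map(fit, const, years = c(2014, 2021))
  expect_named(maps, c("2014", "2021"))
  m14 <- maps[["2014"]]
  expect_s3_class(m14$prediction, "grid_raster")
  expect_true(all(m14$se$values > 0))
  expect_false(any(m14$extrapolation$values > 0))  # constants are in range
  # out-of-range covariate flagged
  hot <- list(tmax = constant_raster(60, 30, 2, "tmax"),
              rain = constant_raster(5, 30, 2, "rain"))
  expect_true(all(predict_map(fit, hot, 2014)[["2014"]]$
                    extrapolation$values > 0))
  # the change between years at a pixel matches the fitted interaction sign
  ch <- maps[["2021"]]$prediction$values - m14$prediction$values
  north_mean <- mean(ch[1:5, ])   # top rows = north
  south_mean <- mean(ch[(nrow(ch) - 4):nrow(ch), ])
  expect_lt(north_mean, south_mean)
})

test_that("a constant-in-time truth yields a near-zero change map", {
  lat <- default_lattice()
  tab <- simulate_trend_table(lat, trend = function(n) 0 * n, rho = 0,
                              noise_sd = 0.05, seed = 55)
  spec <- trend_spec(list(term_smooth("tmax", 8), term_smooth("rain", 8),
                          term_smooth2d(c("x", "y"), 30),
                          term_ti(c("year", "y"), 5),
                          term_smooth("year", 5)), name = "static")
  fit <- suppressWarnings(fit_trend_gam(spec, tab, response = "density",
                                        rho = 0))
  tr <- annual_trend(fit)
  expect_lt(max(abs(tr$change$change)), 0.05)
  # a declining truth yields monotonically declining annual means
  tab2 <- simulate_trend_table(lat, trend = function(n) rep(-0.02,
                                                            length(n)),
                               rho = 0, noise_sd = 0.05, seed = 56)
  fit2 <- suppressWarnings(fit_trend_gam(spec, tab2, response = "density",
                                         rho = 0))
  ann <- annual_trend(fit2)$annual
  expect_true(all(diff(ann$mean_prediction) < 0))
})

test_that("model table assembly computes footprint means and bookkeeping", {
  cm <- compact_lattice_map()
  st <- simulate_study(scene_config(seed = 41), cm$site, cm$lattice,
                       as.Date("2021-07-01"), hours = c(8, 14),
                       scan_interval_min = 60, mapping = cm$mapping)
  sel <- select_scan_per_window(st$profiles_raw, preset_windows()$diel[1, ],
                                band = 500)
  est <- abundance_estimates(st$profiles_filtered, sel,
                             radar_constants(sigma = 1))
  # constant raster: footprint mean equals the constant everywhere
  rs <- list(tmax = constant_raster(17.5, 32.5, 1, "tmax"))
  tab <- assemble_model_table(est, rs, cm$lattice, band = 500)
  expect_true(all(tab$tmax == 17.5))
  expect_equal(nrow(tab), sum(est$band_lower == 500))
  # linear-gradient raster: footprint mean equals the centroid value
  n <- 65
  grad <- grid_raster(matrix(rep(seq(-32, 32, length.out = n), each = n),
                             n, n), -32.5, -32.5, 1, "lin")
  tabg <- assemble_model_table(est, list(tmax = grad), cm$lattice,
                               band = 500)
  centro <- tabg$x
  expect_equal(tabg$tmax, centro, tolerance = 0.15)
  # factors present for the hierarchical terms
  expect_true(all(c("radar", "month", "cell_id", "year") %in% names(tabg)))
})
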