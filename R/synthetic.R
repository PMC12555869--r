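# Synthetic polarimetric scenes with known ground truth: insect layers with
# elongated-target polarimetry and height-declining density, precipitation
# cells, bird-like echoes, clear-air background, diel and seasonal activity
# modulation, covariate fields and trap-count series.

# Truth class codes stored in CLASS matrices.
.TRUE_CLASSES <- c(none = 0L, insect = 1L, precipitation = 2L, bird = 3L,
                   background = 4L)

#' Configure a synthetic scene
#'
#' Defines the generative model painted into synthetic polar volumes. Insect
#' gates carry Z set by the abundance forward model
#' Z = 10 log10(density x sigma_true) - beta, truncated-normal Z_DR above
#' 3 dB (field-typical 2-10 dB for elongated fliers) and low rho_HV, so the
#' depolarization ratio stays far above the -12.5 dB precipitation cut.
#' Precipitation is near-spherical (Z_DR ~ 0.8 dB) and highly correlated
#' (rho_HV ~ 0.99, DR ~ -21 dB); bird-like echoes sit at intermediate Z_DR
#' (~2 dB) so the 3 dB retention cut removes most but not all. A weak
#' clear-air background mixes with the insect return in linear power, which
#' makes the all-echo mean Z_DR track insect activity.
#'
#' @param seed Integer base seed; every generator derives its RNG stream from
#'   it (plus the scan timestamp), so identical configs give bit-identical
#'   output.
#' @param sigma_true Mean single-arthropod radar cross-section painted into
#'   reflectivity, cm^2.
#' @param beta Reflectivity offset used by the forward model, dB.
#' @param insect_layer List: `base_density` (km^-3 at the 100 m band),
#'   `vertical_slope` (km^-3 per 200 m band step, negative), `zdr_mean`,
#'   `zdr_sd`, `zdr_trunc` (dB), `rhohv_range`.
#' @param diel_curve List of two Gaussian activity peaks: `centres` (h),
#'   `widths` (h), `amplitudes`; `NULL` for constant activity 1.
#' @param season_envelope List: `peak_day`, `sd` (days), `start`, `end` (day
#'   of year bounds outside which activity is exactly 0); `NULL` for constant
#'   1.
#' @param precip_cells List: `count`, `radius_km`, `z_range` (dBZ),
#'   `zdr_mean`, `zdr_sd`, `rhohv_mean`, `rhohv_sd`.
#' @param bird_targets List: `count` (gates per volume), `z_range`,
#'   `zdr_mean`, `zdr_sd`, `rhohv_range`.
#' @param background List: `power_dbz`, `zdr_mean`, `zdr_sd`, `rhohv_mean`,
#'   `rhohv_sd`; `NULL` for no background.
#' @param noise_sd Measurement noise SDs: list with `z` (dBZ), `zdr` (dB),
#'   `rhohv`.
#' @param z_min_detect Detection threshold in dBZ; weaker gates are missing.
#' @param spatial_gradient Optional `function(easting, northing)` multiplier
#'   on insect density.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(seed = 1,
                         sigma_true = 1,
                         beta = 26.58,
                         insect_layer = list(),
                         diel_curve = list(),
                         season_envelope = list(),
                         precip_cells = list(),
                         bird_targets = list(),
                         background = list(),
                         noise_sd = list(),
                         z_min_detect = -20,
                         spatial_gradient = NULL) {
  merge_defaults <- function(given, defaults) {
    if (is.null(given)) return(NULL)
    utils::modifyList(defaults, given)
  }
  cfg <- list(
    seed = as.integer(seed), sigma_true = sigma_true, beta = beta,
    insect_layer = merge_defaults(insect_layer, list(
      base_density = 5000, vertical_slope = -450,
      zdr_mean = 6, zdr_sd = 1.5, zdr_trunc = 3,
      rhohv_range = c(0.3, 0.7))),
    diel_curve = merge_defaults(diel_curve, list(
      centres = c(11, 20), widths = c(1.5, 1.2), amplitudes = c(1, 0.8))),
    season_envelope = merge_defaults(season_envelope, list(
      peak_day = 200, sd = 38, start = 60, end = 334)),
    precip_cells = merge_defaults(precip_cells, list(
      count = 0, radius_km = 5, z_range = c(20, 55),
      zdr_mean = 0.8, zdr_sd = 0.2, rhohv_mean = 0.99, rhohv_sd = 0.005)),
    bird_targets = merge_defaults(bird_targets, list(
      count = 0, z_range = c(10, 30), zdr_mean = 2, zdr_sd = 0.3,
      rhohv_range = c(0.5, 0.8))),
    background = merge_defaults(background, list(
      power_dbz = -5, zdr_mean = 0.5, zdr_sd = 0.3,
      rhohv_mean = 0.9, rhohv_sd = 0.03)),
    noise_sd = merge_defaults(noise_sd, list(z = 0.5, zdr = 0.2,
                                             rhohv = 0.01)),
    z_min_detect = z_min_detect,
    spatial_gradient = spatial_gradient)
  stopifnot(cfg$sigma_true > 0, cfg$insect_layer$base_density >= 0)
  structure(cfg, class = "scene_config")
}

#' Diel activity multiplier
#' @param config A `scene_config`.
#' @param hour Fractional hour(s) of day.
#' @return Multiplier in [0, ~1] (1 when `diel_curve` is `NULL`).
#' @export
diel_multiplier <- function(config, hour) {
  dc <- config$diel_curve
  if (is.null(dc)) return(rep(1, length(hour)))
  out <- 0
  for (i in seq_along(dc$centres)) {
    d <- abs(hour - dc$centres[i])
    d <- pmin(d, 24 - d)
    out <- out + dc$amplitudes[i] * exp(-d^2 / (2 * dc$widths[i]^2))
  }
  out
}

#' Seasonal activity multiplier
#' @param config A `scene_config`.
#' @param doy Day(s) of year.
#' @return Multiplier in [0, 1]; exactly 0 outside the season bounds.
#' @export
season_multiplier <- function(config, doy) {
  se <- config$season_envelope
  if (is.null(se)) return(rep(1, length(doy)))
  out <- exp(-(doy - se$peak_day)^2 / (2 * se$sd^2))
  out[doy < se$start | doy > se$end] <- 0
  out
}

# truncated-normal draw above `lower`
.rtrunc_norm <- function(n, mean, sd, lower) {
  p0 <- stats::pnorm(lower, mean, sd)
  stats::qnorm(p0 + stats::runif(n) * (1 - p0), mean, sd)
}

# deterministic per-volume seed from the config seed and the timestamp
.volume_seed <- function(config, timestamp) {
  as.integer((config$seed * 97 + round(as.numeric(timestamp) / 60)) %%
               .Machine$integer.max)
}

#' Simulate one polar volume
#'
#' Paints a full polar volume at one timestamp. Insect density in band b at
#' time t is `max(0, base_density + vertical_slope * b) x diel(t) x
#' season(t)` (x the spatial gradient if given); insect and background
#' returns mix in linear power (reflectivities add; Z_DR and rho_HV combine
#' power-weighted), precipitation cells and bird gates override. Gates below
#' the detection threshold are missing. Deterministic given config and
#' timestamp.
#'
#' @param config A [scene_config()].
#' @param site A `radar_site`.
#' @param lattice Optional `cvp_lattice`; when given, a per-(cell, band)
#'   truth slice is attached.
#' @param timestamp Scan time (`POSIXct`, UTC).
#' @return A `polar_volume` whose sweeps carry a truth `CLASS` matrix
#'   (0 none, 1 insect, 2 precipitation, 3 bird, 4 background); attribute
#'   `truth` holds the per-(cell, band) true density table when a lattice was
#'   supplied.
#' @export
simulate_scan_volume <- function(config, site, lattice = NULL, timestamp) {
  stopifnot(inherits(config, "scene_config"), inherits(site, "radar_site"))
  timestamp <- as.POSIXct(timestamp, tz = "UTC")
  set.seed(.volume_seed(config, timestamp))
  hour <- as.numeric(format(timestamp, "%H")) +
    as.numeric(format(timestamp, "%M")) / 60
  doy <- as.numeric(format(timestamp, "%j"))
  activity <- diel_multiplier(config, hour) * season_multiplier(config, doy)

  n_rng <- floor(site$max_range * 1000 / site$gate_length)
  rng <- (seq_len(n_rng) - 0.5) * site$gate_length / 1000
  az <- seq(0, 360 - site$azimuth_step, by = site$azimuth_step) +
    site$azimuth_step / 2
  naz <- length(az)
  il <- config$insect_layer
  bg <- config$background
  pc <- config$precip_cells
  bt <- config$bird_targets
  # per-volume precipitation cell centres
  precip_xy <- if (!is.null(pc) && pc$count > 0) {
    cbind(stats::runif(pc$count, -27.5, 27.5),
          stats::runif(pc$count, -27.5, 27.5))
  } else NULL

  sweeps <- vector("list", length(site$elevation_angles))
  for (k in seq_along(site$elevation_angles)) {
    el <- site$elevation_angles[k]
    g <- rng * cos(el * pi / 180)
    e <- outer(sin(az * pi / 180), g)
    n <- outer(cos(az * pi / 180), g)
    h <- matrix(beam_height(rng, el, 0), naz, n_rng, byrow = TRUE)
    band_idx <- floor((h - 100) / 200)
    in_layer <- h >= 100 & h < 2100
    dens <- matrix(0, naz, n_rng)
    dens[in_layer] <- pmax(0, il$base_density +
                             il$vertical_slope * band_idx[in_layer])
    dens <- dens * activity
    if (!is.null(config$spatial_gradient)) {
      dens <- dens * config$spatial_gradient(e, n)
    }
    p_ins <- dens * config$sigma_true * 10^(-config$beta / 10)
    p_bg <- if (is.null(bg)) matrix(0, naz, n_rng) else {
      matrix(10^(bg$power_dbz / 10), naz, n_rng)
    }
    ng <- naz * n_rng
    zeta_ins <- 10^(.rtrunc_norm(ng, il$zdr_mean, il$zdr_sd,
                                 il$zdr_trunc) / 10)
    rho_ins <- stats::runif(ng, il$rhohv_range[1], il$rhohv_range[2])
    zeta_bg <- 10^(stats::rnorm(ng, bg$zdr_mean %||% 0,
                                bg$zdr_sd %||% 0) / 10)
    rho_bg <- if (is.null(bg)) rep(0, ng) else {
      pmin(1, pmax(0, stats::rnorm(ng, bg$rhohv_mean, bg$rhohv_sd)))
    }
    p_tot <- p_ins + p_bg
    denom_v <- p_ins / zeta_ins + p_bg / zeta_bg
    z <- ifelse(p_tot > 0, 10 * log10(p_tot), NA_real_)
    zdr <- ifelse(p_tot > 0, 10 * log10(p_tot / denom_v), NA_real_)
    rho <- ifelse(p_tot > 0, (p_ins * rho_ins + p_bg * rho_bg) / p_tot, NA_real_)
    cls <- matrix(.TRUE_CLASSES[["none"]], naz, n_rng)
    cls[p_bg > 0] <- .TRUE_CLASSES[["background"]]
    cls[p_ins > p_bg] <- .TRUE_CLASSES[["insect"]]
    dim(z) <- dim(zdr) <- dim(rho) <- c(naz, n_rng)

    if (!is.null(precip_xy)) {
      inside <- matrix(FALSE, naz, n_rng)
      for (j in seq_len(nrow(precip_xy))) {
        inside <- inside | ((e - precip_xy[j, 1])^2 +
                              (n - precip_xy[j, 2])^2 <= pc$radius_km^2)
      }
      np <- sum(inside)
      if (np) {
        z[inside] <- stats::runif(np, pc$z_range[1], pc$z_range[2])
        zdr[inside] <- stats::rnorm(np, pc$zdr_mean, pc$zdr_sd)
        rho[inside] <- pmin(1, pmax(0, stats::rnorm(np, pc$rhohv_mean,
                                                    pc$rhohv_sd)))
        cls[inside] <- .TRUE_CLASSES[["precipitation"]]
      }
    }
    if (!is.null(bt) && bt$count > 0) {
      pick <- sample.int(ng, min(bt$count, ng))
      z[pick] <- stats::runif(length(pick), bt$z_range[1], bt$z_range[2])
      zdr[pick] <- stats::rnorm(length(pick), bt$zdr_mean, bt$zdr_sd)
      rho[pick] <- stats::runif(length(pick), bt$rhohv_range[1],
                                bt$rhohv_range[2])
      cls[pick] <- .TRUE_CLASSES[["bird"]]
    }
    ns <- config$noise_sd
    if (ns$z > 0) z <- z + stats::rnorm(ng, 0, ns$z)
    if (ns$zdr > 0) zdr <- zdr + stats::rnorm(ng, 0, ns$zdr)
    if (ns$rhohv > 0) rho <- pmin(pmax(rho + stats::rnorm(ng, 0, ns$rhohv),
                                       0), 1)
    undetected <- is.na(z) | z < config$z_min_detect
    z[undetected] <- NA_real_
    zdr[undetected] <- NA_real_
    rho[undetected] <- NA_real_
    sweeps[[k]] <- list(elevation = el, Z = z, ZDR = zdr, RHOHV = rho,
                        CLASS = cls)
  }
  vol <- polar_volume(site, timestamp, sweeps)
  if (!is.null(lattice)) {
    ret <- retained_cells(lattice)
    grad <- if (is.null(config$spatial_gradient)) 1 else {
      config$spatial_gradient(ret$easting_km, ret$northing_km)
    }
    truth <- expand.grid(cell_id = ret$cell_id,
                         band_lower = height_band_edges(),
                         stringsAsFactors = FALSE)
    b_idx <- (truth$band_lower - 100) / 200
    g_cell <- if (length(grad) == 1) 1 else grad[match(truth$cell_id,
                                                       ret$cell_id)]
    truth$true_density <- pmax(0, il$base_density +
                                 il$vertical_slope * b_idx) *
      activity * g_cell
    truth$timestamp <- timestamp
    attr(vol, "truth") <- truth
  }
  attr(vol, "activity") <- activity
  vol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multi-day study
#'
#' Generates volumes at a fixed scan interval over the requested dates and
#' hours, modulating insect density by the diel curve and seasonal envelope,
#' and streams each volume through classification and profiling (volumes are
#' discarded unless `keep_volumes = TRUE`, keeping long runs in bounded
#' memory).
#'
#' @param config A [scene_config()].
#' @param site A `radar_site`.
#' @param lattice A `cvp_lattice`.
#' @param dates `Date` vector (at least one day).
#' @param hours Numeric `c(first, last)` whole-hour range scanned per day
#'   (inclusive start, exclusive end).
#' @param scan_interval_min Minutes between volumes (default: site setting).
#' @param filter_cfg A [filter_config()].
#' @param min_gates Valid-band threshold for profiles.
#' @param mapping Optional precomputed `gate_map`.
#' @param keep_volumes Keep the simulated volumes in the result.
#' @return A `study_archive` list: `profiles_raw` (all detected echoes),
#'   `profiles_filtered` (arthropod gates), `truth` (per cell/band/scan true
#'   density), `label_counts` (summed filter labels), `volumes` (optional),
#'   plus the config/site/lattice/mapping used.
#' @export
simulate_study <- function(config, site, lattice, dates,
                           hours = c(0, 24),
                           scan_interval_min = site$scan_interval,
                           filter_cfg = filter_config(),
                           min_gates = 3,
                           mapping = NULL,
                           keep_volumes = FALSE) {
  dates <- as.Date(dates)
  if (!length(dates)) stop("empty date range")
  if (is.null(mapping)) mapping <- assign_gates_to_columns(lattice, site)
  offsets <- seq(hours[1] * 60, hours[2] * 60 - 1, by = scan_interval_min)
  raw <- filt <- truth <- vector("list", length(dates) * length(offsets))
  vols <- if (keep_volumes) list() else NULL
  counts <- NULL
  i <- 0
  for (d in seq_along(dates)) {
    day0 <- as.POSIXct(paste(dates[d], "00:00:00"), tz = "UTC")
    for (off in offsets) {
      i <- i + 1
      stamp <- day0 + off * 60
      vol <- simulate_scan_volume(config, site, lattice, stamp)
      truth[[i]] <- attr(vol, "truth")
      raw[[i]] <- build_profile(vol, mapping, min_gates = min_gates)
      fv <- filter_volume(vol, filter_cfg)
      lc <- attr(fv, "label_counts")
      counts <- if (is.null(counts)) lc else counts + lc
      filt[[i]] <- build_profile(fv, mapping, min_gates = min_gates)
      if (keep_volumes) vols[[length(vols) + 1]] <- vol
    }
  }
  bind <- function(lst) {
    out <- do.call(rbind, lst)
    out <- out[out$band_valid, , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("cvp_profile", "data.frame")
    out
  }
  structure(list(profiles_raw = bind(raw), profiles_filtered = bind(filt),
                 truth = do.call(rbind, truth), label_counts = counts,
                 volumes = vols, config = config, site = site,
                 lattice = lattice, mapping = mapping),
            class = "study_archive")
}

#' @export
print.study_archive <- function(x, ...) {
  cat("Synthetic study archive:", nrow(x$profiles_raw), "raw and",
      nrow(x$profiles_filtered), "filtered profile rows\n")
  if (!is.null(x$label_counts)) {
    cat("  gate labels:\n")
    print(x$label_counts)
  }
  invisible(x)
}

#' Sample single-class polarimetric gates
#'
#' Draws gate-level (Z, Z_DR, rho_HV) triplets from one class's generative
#' distribution (without power mixing), with measurement noise. Used to
#' calibrate the filter thresholds against the class distributions.
#'
#' @param n Number of gates.
#' @param config A [scene_config()].
#' @param class One of `"insect"`, `"precipitation"`, `"bird"`.
#' @param activity Insect activity multiplier (affects Z only).
#' @param band Height band lower edge for the insect density (default 500).
#' @param seed RNG seed (default from the config).
#' @return Data frame with `z`, `zdr`, `rho_hv`.
#' @export
sample_gates <- function(n, config, class = c("insect", "precipitation",
                                              "bird"),
                         activity = 1, band = 500, seed = config$seed) {
  class <- match.arg(class)
  set.seed(seed)
  il <- config$insect_layer
  out <- switch(class,
    insect = {
      d <- pmax(0, il$base_density + il$vertical_slope * (band - 100) / 200) *
        activity
      data.frame(
        z = rep(10 * log10(d * config$sigma_true) - config$beta, n),
        zdr = .rtrunc_norm(n, il$zdr_mean, il$zdr_sd, il$zdr_trunc),
        rho_hv = stats::runif(n, il$rhohv_range[1], il$rhohv_range[2]))
    },
    precipitation = {
      pc <- config$precip_cells
      data.frame(z = stats::runif(n, pc$z_range[1], pc$z_range[2]),
                 zdr = stats::rnorm(n, pc$zdr_mean, pc$zdr_sd),
                 rho_hv = pmin(1, pmax(0, stats::rnorm(n, pc$rhohv_mean,
                                                       pc$rhohv_sd))))
    },
    bird = {
      bt <- config$bird_targets
      data.frame(z = stats::runif(n, bt$z_range[1], bt$z_range[2]),
                 zdr = stats::rnorm(n, bt$zdr_mean, bt$zdr_sd),
                 rho_hv = stats::runif(n, bt$rhohv_range[1],
                                       bt$rhohv_range[2]))
    })
  ns <- config$noise_sd
  out$z <- out$z + stats::rnorm(n, 0, ns$z)
  out$zdr <- out$zdr + stats::rnorm(n, 0, ns$zdr)
  out$rho_hv <- pmin(1, pmax(0, out$rho_hv + stats::rnorm(n, 0, ns$rhohv)))
  out
}

# smooth random field in [0, 1]: Gaussian-filtered white noise, min-max
# rescaled
.gauss_field <- function(n, sigma_cells = 6) {
  x <- matrix(stats::rnorm((n + 6 * sigma_cells)^2),
              n + 6 * sigma_cells, n + 6 * sigma_cells)
  kern <- stats::dnorm(seq(-3 * sigma_cells, 3 * sigma_cells), 0, sigma_cells)
  kern <- kern / sum(kern)
  x <- apply(x, 2, function(col) stats::filter(col, kern, sides = 2))
  x <- t(apply(x, 1, function(row) stats::filter(row, kern, sides = 2)))
  x <- x[3 * sigma_cells + seq_len(n), 3 * sigma_cells + seq_len(n)]
  (x - min(x)) / (max(x) - min(x))
}

#' Generate covariate rasters with known effect functions
#'
#' Smooth random fields (Gaussian-filtered white noise) scaled to realistic
#' covariate ranges: Tmax (degC), Rain (mm), Wind (m/s), ALAN (DN 0-63),
#' Elevation (m), and percentage land cover for arable, woodland, grassland
#' and urban classes (clipped to [0, 100], summing to <= 100 per pixel). The
#' supplied effect functions are carried through as ground truth for
#' trend-model recovery runs.
#'
#' @param config A [scene_config()] (its seed fixes the fields).
#' @param half_extent Half-width of the square extent (km).
#' @param cellsize Cell size (km).
#' @param effects Named list of effect functions on covariate scale; stored
#'   as truth.
#' @return List with `rasters` (named `grid_raster` list) and `effects`.
#' @export
generate_covariate_rasters <- function(config, half_extent = 32.5,
                                       cellsize = 1, effects = list()) {
  set.seed(config$seed + 7919L)
  n <- ceiling(2 * half_extent / cellsize)
  mk <- function(v, name) grid_raster(v, -half_extent, -half_extent,
                                      cellsize, name)
  f <- function() .gauss_field(n)
  rasters <- list(
    tmax = mk(12 + 12 * f(), "tmax"),
    rain = mk(10 * f(), "rain"),
    wind = mk(15 * f(), "wind"),
    alan = mk(63 * f()^2, "alan"),
    elevation = mk(400 * f(), "elevation"))
  lc <- lapply(1:5, function(i) exp(3 * f()))  # 4 classes + "other"
  tot <- Reduce(`+`, lc)
  lc_names <- c("arable", "woodland", "grassland", "urban")
  for (i in seq_along(lc_names)) {
    rasters[[lc_names[i]]] <- mk(pmin(pmax(100 * lc[[i]] / tot, 0), 100),
                                 lc_names[i])
  }
  list(rasters = rasters, effects = effects)
}

#' Simulate daily suction-trap counts coupled to near-ground truth
#'
#' Daily trap count = `scaling` x the mean true density in the lowest height
#' band that day x multiplicative lognormal noise. Heavy-rain days are
#' flagged (their counts are perturbed upwards to mimic the contaminated
#' radar estimates that motivate their exclusion).
#'
#' @param truth Truth table from a [simulate_study()] archive.
#' @param scaling Trap-to-aerial-density scaling.
#' @param noise_sd_log SD of the lognormal noise on the log scale (0 = exact
#'   coupling).
#' @param rain_days `Date` vector of flagged rain days.
#' @param seed RNG seed.
#' @return Data frame with `date`, `count`, `rain`.
#' @export
simulate_trap_counts <- function(truth, scaling = 1, noise_sd_log = 0,
                                 rain_days = as.Date(character()), seed = 1) {
  set.seed(seed)
  date <- as.Date(truth$timestamp, tz = "UTC")
  low <- truth$band_lower == min(truth$band_lower)
  d <- tapply(truth$true_density[low], date[low], mean)
  out <- data.frame(date = as.Date(names(d)), count = as.numeric(d) * scaling)
  if (noise_sd_log > 0) {
    out$count <- out$count * exp(stats::rnorm(nrow(out), 0, noise_sd_log))
  }
  out$rain <- out$date %in% as.Date(rain_days)
  out$count[out$rain] <- out$count[out$rain] * exp(1)
  rownames(out) <- NULL
  out
}

#' Simulate a trap/radar validation series with height-decaying coupling
#'
#' Generates daily trap counts and per-band radar density estimates sharing a
#' common daily activity signal whose loading decreases linearly with height:
#' band b carries loading `alpha[b]`, the trap `trap_alpha`. The standardized
#' OLS slope (= Pearson r) between trap and band therefore decreases with
#' height by construction, emulating the decoupling of elevated layers from
#' ground-level catches.
#'
#' @param n_days Number of days.
#' @param bands Band lower edges (default the 10 CVP bands).
#' @param alpha Per-band loadings on the common signal (defaults linear from
#'   0.9 at the lowest to 0.1 at the highest band).
#' @param trap_alpha Trap loading on the common signal.
#' @param n_rain Number of flagged rain days.
#' @param seed RNG seed.
#' @return List with `trap` (`date`, `count`, `rain`), `estimates` (`date`,
#'   `band_lower`, `density`) and `alpha`.
#' @export
simulate_validation_series <- function(n_days = 116,
                                       bands = height_band_edges(),
                                       alpha = seq(0.9, 0.1,
                                                   length.out = length(bands)),
                                       trap_alpha = 0.95, n_rain = 9,
                                       seed = 1) {
  set.seed(seed)
  common <- stats::rnorm(n_days)
  dates <- as.Date("2021-04-15") + seq_len(n_days) - 1
  trap_sig <- trap_alpha * common +
    sqrt(1 - trap_alpha^2) * stats::rnorm(n_days)
  trap <- data.frame(date = dates, count = exp(3 + 0.5 * trap_sig))
  trap$rain <- seq_len(n_days) %in% sample.int(n_days, n_rain)
  trap$count[trap$rain] <- trap$count[trap$rain] * exp(2)
  est <- lapply(seq_along(bands), function(b) {
    sig <- alpha[b] * common + sqrt(1 - alpha[b]^2) * stats::rnorm(n_days)
    data.frame(date = dates, band_lower = bands[b],
               density = exp(8 - 0.1 * b + 0.5 * sig))
  })
  list(trap = trap, estimates = do.call(rbind, est), alpha = alpha)
}

#' Simulate a modelling table with known smooth effects and AR(1) noise
#'
#' Generates a per-(cell, time) abundance table from a known additive truth:
#' response = intercept + effect(tmax) + effect(rain) + spatial(x, y) +
#' trend(northing) x (year - mid-year) + AR(1) noise within each cell's time
#' series. Covariates are drawn independently per observation so effect
#' recovery is unconfounded. The north-south trend interaction gives a
#' spatially signed change map as ground truth.
#'
#' @param lattice A `cvp_lattice` (its retained cells are the sites).
#' @param years Years covered.
#' @param n_per_year Observations per cell per year.
#' @param effects Named list of truth effect functions `tmax`, `rain`.
#' @param spatial Truth spatial surface `function(x, y)`.
#' @param trend Per-year trend slope as a function of northing (negative in
#'   the north, positive in the south by default).
#' @param rho AR(1) correlation of the within-cell noise.
#' @param noise_sd Innovation SD of the AR(1) noise.
#' @param intercept Truth intercept.
#' @param seed RNG seed.
#' @return Model table with `cell_id`, `x`, `y`, `year`, `date`, `radar`,
#'   `month`, `tmax`, `rain`, `density` (response, linear scale so that
#'   log10(density + 1) equals the additive truth plus noise) and truth
#'   columns `mu_true` (noiseless linear predictor) and `trend_true`
#'   (per-cell change over the full year span); attribute `effects` echoes
#'   the truth functions.
#' @export
simulate_trend_table <- function(lattice,
                                 years = 2014:2021,
                                 n_per_year = 2,
                                 effects = list(
                                   tmax = function(x) 0.4 * tanh((x - 18) / 4),
                                   rain = function(x) -0.03 * x),
                                 spatial = function(x, y)
                                   0.4 * sin(x / 15) * cos(y / 15),
                                 trend = function(northing) -0.004 * northing,
                                 rho = 0.6, noise_sd = 0.3,
                                 intercept = 5, seed = 1) {
  set.seed(seed)
  ret <- retained_cells(lattice)
  nt <- length(years) * n_per_year
  grid <- expand.grid(obs = seq_len(n_per_year), year = years,
                      cell = seq_len(nrow(ret)))
  n <- nrow(grid)
  tab <- data.frame(
    cell_id = ret$cell_id[grid$cell],
    x = ret$easting_km[grid$cell], y = ret$northing_km[grid$cell],
    year = grid$year,
    date = as.Date(sprintf("%d-06-01", grid$year)) + 30 * (grid$obs - 1),
    radar = factor(ret$site_id[grid$cell]),
    tmax = stats::rnorm(n, 18, 4),
    rain = stats::rexp(n, 1 / 5),
    stringsAsFactors = FALSE)
  tab$month <- factor(format(tab$date, "%m"))
  mid <- mean(range(years))
  mu <- intercept + effects$tmax(tab$tmax) + effects$rain(tab$rain) +
    spatial(tab$x, tab$y) + trend(tab$y) * (tab$year - mid)
  # AR(1) noise per cell over its time-ordered observations
  eps <- unlist(lapply(seq_len(nrow(ret)), function(i) {
    if (rho == 0) return(stats::rnorm(nt, 0, noise_sd))
    as.numeric(stats::arima.sim(list(ar = rho), nt, sd = noise_sd))
  }))
  ord <- order(tab$cell_id, tab$date)
  tab <- tab[ord, , drop = FALSE]
  mu <- mu[ord]
  tab$mu_true <- mu
  tab$trend_true <- trend(tab$y) * diff(range(years))
  tab$density <- pmax(0, 10^(mu + eps) - 1)
  tab$cell_id <- factor(tab$cell_id)
  rownames(tab) <- NULL
  attr(tab, "effects") <- effects
  attr(tab, "spatial") <- spatial
  attr(tab, "trend") <- trend
  attr(tab, "rho") <- rho
  tab
}
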