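# Reflectivity-to-abundance conversion and derived summaries: eta = Z + beta,
# division by the mean radar cross-section, vertical gradients, regional
# extrapolation, suction-trap validation.

#' Rayleigh reflectivity offset beta
#'
#' The offset converting reflectivity factor (dBZ) to reflectivity eta (dB of
#' cm^2 km^-3): beta = 10 log10(10^3 pi^5 |K_m|^2 / lambda^4) with lambda in
#' cm. At lambda = 5.0 cm and |K_m|^2 = 0.93 this evaluates to 26.58 dB, the
#' constant used operationally for the UK C-band network.
#'
#' @param wavelength Radar wavelength in cm (> 0).
#' @param dielectric_factor |K_m|^2 of the scatterer medium (default 0.93,
#'   liquid water).
#' @return beta in dB.
#' @export
compute_beta <- function(wavelength = 5.0, dielectric_factor = 0.93) {
  if (any(wavelength <= 0)) stop("wavelength must be positive")
  10 * log10(1e3 * pi^5 * dielectric_factor / wavelength^4)
}

#' Radar constants for abundance conversion
#'
#' Collects the conversion constants. `sigma`, the mean radar cross-section of
#' a single arthropod in cm^2, has no default and must be supplied: it is a
#' study-specific calibration, not a property of the radar. `beta` may be
#' given directly (operational constant 26.58 dB) or computed from the
#' wavelength via [compute_beta()]; the path taken is recorded.
#'
#' @param sigma Mean single-arthropod radar cross-section, cm^2 (> 0).
#' @param beta Reflectivity offset in dB, or `NULL` to compute from
#'   `wavelength`.
#' @param wavelength Wavelength in cm, used when `beta` is `NULL`.
#' @param dielectric_factor |K_m|^2 used when computing beta.
#' @param cvp_radius_km Column radius (km), default 2.5.
#' @param band_depth_km Band depth (km), default 0.2.
#' @return An object of class `radar_constants` with `sigma`, `beta`,
#'   `beta_source`, and the band volume `v_h` = pi r^2 h in km^3.
#' @export
radar_constants <- function(sigma, beta = 26.58, wavelength = NULL,
                            dielectric_factor = 0.93,
                            cvp_radius_km = 2.5, band_depth_km = 0.2) {
  if (missing(sigma) || is.null(sigma) || !is.finite(sigma) || sigma <= 0) {
    stop("sigma (mean radar cross-section, cm^2) must be supplied and > 0")
  }
  if (is.null(beta)) {
    if (is.null(wavelength)) stop("give either beta or wavelength")
    beta <- compute_beta(wavelength, dielectric_factor)
    src <- sprintf("computed from wavelength %.2f cm, |K|^2 = %.3f",
                   wavelength, dielectric_factor)
  } else {
    src <- "supplied directly"
  }
  structure(list(sigma = sigma, beta = beta, beta_source = src,
                 cvp_radius_km = cvp_radius_km, band_depth_km = band_depth_km,
                 v_h = pi * cvp_radius_km^2 * band_depth_km),
            class = "radar_constants")
}

#' @export
print.radar_constants <- function(x, ...) {
  cat("Radar constants: beta =", round(x$beta, 2), "dB (", x$beta_source,
      "), sigma =", x$sigma, "cm^2, V_h =", round(x$v_h, 4), "km^3\n")
  invisible(x)
}

#' Convert band mean reflectivity to arthropod density
#'
#' eta_dB = Z + beta; eta_lin = 10^(eta_dB/10) cm^2 km^-3 is the backscatter
#' cross-section per unit air volume. Multiplying by the band volume V_h gives
#' the total backscattering area, and dividing by sigma the head count; the
#' volume density is therefore eta_lin / sigma, independent of V_h.
#'
#' @param mean_z Band mean reflectivity factor(s) in dBZ.
#' @param constants A [radar_constants()].
#' @return Data frame with `eta_db`, `density` (individuals km^-3) and
#'   `total_count` (individuals in the band volume).
#' @export
band_abundance <- function(mean_z, constants) {
  stopifnot(inherits(constants, "radar_constants"))
  eta_db <- mean_z + constants$beta
  eta_lin <- 10^(eta_db / 10)
  density <- eta_lin / constants$sigma
  data.frame(eta_db = eta_db, density = density,
             total_count = density * constants$v_h)
}

#' Abundance estimates for selected scans
#'
#' Joins per-window scan selections to the filtered profile table and converts
#' every valid band of each selected scan.
#'
#' @param profiles Filtered-profile `cvp_profile` table (arthropod gates).
#' @param selection Scan selection from [select_scan_per_window()].
#' @param constants A [radar_constants()].
#' @return An `abundance_estimate` data frame: `site_id`, `cell_id`, `date`,
#'   `window`, `band_lower`, `mean_z`, `eta_db`, `density`, `total_count`.
#' @export
abundance_estimates <- function(profiles, selection, constants) {
  if (!nrow(selection)) {
    out <- data.frame(site_id = character(), cell_id = character(),
                      date = as.Date(character()), window = character(),
                      band_lower = numeric(), mean_z = numeric(),
                      eta_db = numeric(), density = numeric(),
                      total_count = numeric())
    class(out) <- c("abundance_estimate", "data.frame")
    return(out)
  }
  keep <- merge(profiles[profiles$band_valid, , drop = FALSE],
                selection[, c("cell_id", "window", "timestamp")],
                by = c("cell_id", "timestamp"))
  conv <- band_abundance(keep$mean_z, constants)
  out <- data.frame(site_id = keep$site_id, cell_id = keep$cell_id,
                    date = as.Date(keep$timestamp, tz = "UTC"),
                    window = keep$window, band_lower = keep$band_lower,
                    mean_z = keep$mean_z, conv, stringsAsFactors = FALSE)
  out <- out[order(out$date, out$window, out$cell_id, out$band_lower), ]
  rownames(out) <- NULL
  class(out) <- c("abundance_estimate", "data.frame")
  out
}

#' Vertical abundance gradient
#'
#' Ordinary least-squares slope of abundance against band index (one unit =
#' one 200 m step), with standard error, adjusted R^2 and p-value.
#'
#' @param band_lower Band lower edges in m.
#' @param abundance Abundance (count or density) per band observation.
#' @return List with `slope` (per 200 m), `se`, `adj_r2`, `p`, `n`.
#' @export
vertical_gradient <- function(band_lower, abundance) {
  ok <- is.finite(band_lower) & is.finite(abundance)
  if (length(unique(band_lower[ok])) < 3) {
    stop("need at least 3 distinct bands")
  }
  band_index <- (band_lower[ok] - 100) / 200
  fit <- stats::lm(abundance[ok] ~ band_index)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       se = s$coefficients[2, 2],
       adj_r2 = s$adj.r.squared,
       p = s$coefficients[2, 4],
       n = sum(ok))
}

#' Extrapolate a mean density to a region
#'
#' total = mean_density x region_area x band_depth.
#'
#' @param mean_density Mean volume density, individuals km^-3.
#' @param region_area_km2 Region area in km^2.
#' @param band_depth_km Band depth in km (default 0.2).
#' @return Total individuals over the region in the band.
#' @export
extrapolate_region <- function(mean_density, region_area_km2,
                               band_depth_km = 0.2) {
  stopifnot(mean_density >= 0, region_area_km2 > 0, band_depth_km > 0)
  mean_density * region_area_km2 * band_depth_km
}

#' Validate radar estimates against suction-trap counts
#'
#' Per height band, regresses standardized (z-scored) daily radar abundance on
#' the standardized trap count over overlapping non-rain days: on standardized
#' variables the OLS slope equals the Pearson correlation.
#'
#' @param trap Data frame with `date` and `count` (daily trap totals).
#' @param estimates Data frame with `date`, `band_lower`, `density` (daily
#'   radar estimates, e.g. one window of an `abundance_estimate`).
#' @param rain_days Dates excluded as heavy-rain days.
#' @param min_days Minimum overlapping non-rain days required (default 10).
#' @return Data frame per band: `band_lower`, `slope` (= Pearson r), `se`,
#'   `adj_r2`, `p`, `n_days`.
#' @export
trap_validation_ols <- function(trap, estimates, rain_days = as.Date(character()),
                                min_days = 10) {
  trap <- trap[!(as.Date(trap$date) %in% as.Date(rain_days)), , drop = FALSE]
  bands <- sort(unique(estimates$band_lower))
  rows <- lapply(bands, function(b) {
    est <- estimates[estimates$band_lower == b, , drop = FALSE]
    m <- merge(trap, est, by = "date")
    m <- m[is.finite(m$count) & is.finite(m$density), , drop = FALSE]
    if (nrow(m) < min_days) {
      stop(sprintf("band %g: only %d overlapping non-rain days (min %d)",
                   b, nrow(m), min_days))
    }
    x <- as.numeric(scale(m$count))
    y <- as.numeric(scale(m$density))
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    data.frame(band_lower = b, slope = unname(stats::coef(fit)[2]),
               se = s$coefficients[2, 2], adj_r2 = s$adj.r.squared,
               p = s$coefficients[2, 4], n_days = nrow(m))
  })
  do.call(rbind, rows)
}

#' Write abundance estimates as CSV
#' @param estimates An `abundance_estimate` data frame.
#' @param constants The [radar_constants()] used (echoed into the file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(estimates, constants, path) {
  out <- as.data.frame(estimates)
  out$sigma_cm2 <- rep(constants$sigma, nrow(out))
  out$beta_db <- rep(constants$beta, nrow(out))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
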