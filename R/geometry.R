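# Radar scan geometry: beam propagation, CVP lattice, gate assignment,
# terrain blockage.

# Effective earth radius (4/3 refraction model), km
.EFFECTIVE_EARTH_RADIUS_KM <- 4 / 3 * 6371

# CVP lattice constants: 12 x 12 grid of 2.5 km-radius columns on 5 km
# spacing, i.e. a 60 x 60 km box centred on the radar.
.CVP_GRID_DIM <- 12L
.CVP_SPACING_KM <- 5
.CVP_RADIUS_KM <- 2.5

# Height bands: ten half-open 200 m bands between 100 and 2100 m above the
# radar ground reference, addressed by their lower edge.
.BAND_LOWER_M <- seq(100, 1900, by = 200)
.BAND_DEPTH_M <- 200

#' Describe a weather-surveillance radar site
#'
#' Bundles the scan geometry of one dual-polarization radar. Defaults match a
#' C-band operational network radar: 5.3 cm wavelength, 1.1 degree beam,
#' plan-position-indicator sweeps at elevations 0.5-4.0 degrees, 600 m range
#' gates, 1 degree azimuth sectors, 250 km range, one volume every 5 minutes.
#'
#' @param site_id Character site identifier.
#' @param latitude,longitude Site coordinates in decimal degrees.
#' @param antenna_altitude Antenna altitude in metres above sea level.
#' @param wavelength Radar wavelength in cm.
#' @param beam_width Half-power beam width in degrees.
#' @param elevation_angles Strictly increasing elevation angles in degrees,
#'   each in (0, 90).
#' @param gate_length Range-gate length in metres.
#' @param azimuth_step Azimuth sector width in degrees (must divide 360).
#' @param max_range Maximum range in km.
#' @param scan_interval Volume repeat interval in minutes.
#' @return An object of class `radar_site`.
#' @export
radar_site <- function(site_id = "radar",
                       latitude = 51.5, longitude = -0.5,
                       antenna_altitude = 50,
                       wavelength = 5.3,
                       beam_width = 1.1,
                       elevation_angles = seq(0.5, 4.0, by = 0.5),
                       gate_length = 600,
                       azimuth_step = 1,
                       max_range = 250,
                       scan_interval = 5) {
  stopifnot(wavelength > 0, gate_length > 0, max_range > 0,
            azimuth_step > 0, 360 %% azimuth_step == 0)
  if (any(diff(elevation_angles) <= 0) ||
      any(elevation_angles <= 0) || any(elevation_angles >= 90)) {
    stop("elevation_angles must be strictly increasing and in (0, 90) degrees")
  }
  structure(
    list(site_id = site_id, latitude = latitude, longitude = longitude,
         antenna_altitude = antenna_altitude, wavelength = wavelength,
         beam_width = beam_width, elevation_angles = elevation_angles,
         gate_length = gate_length, azimuth_step = azimuth_step,
         max_range = max_range, scan_interval = scan_interval),
    class = "radar_site")
}

#' @export
print.radar_site <- function(x, ...) {
  cat("Radar site <", x$site_id, ">  (", x$latitude, "N, ", x$longitude,
      "E, antenna ", x$antenna_altitude, " m ASL)\n", sep = "")
  cat("  wavelength ", x$wavelength, " cm, beam ", x$beam_width,
      " deg, gates ", x$gate_length, " m x ", x$azimuth_step,
      " deg, range ", x$max_range, " km\n", sep = "")
  cat("  elevations:", paste(x$elevation_angles, collapse = ", "),
      "deg; volume every", x$scan_interval, "min\n")
  invisible(x)
}

#' Height band edges used by columnar vertical profiles
#'
#' Ten half-open 200 m deep bands between 100 and 2100 m above the radar
#' ground reference; a band is addressed by its lower edge.
#'
#' @return Numeric vector of lower band edges in metres.
#' @export
height_band_edges <- function() .BAND_LOWER_M

#' Height band containing a given height
#'
#' @param height_m Height(s) above the radar ground reference in metres.
#' @return The lower edge of the containing band (m), or `NA` when the height
#'   falls outside [100, 2100).
#' @export
height_band_of <- function(height_m) {
  idx <- floor((height_m - 100) / .BAND_DEPTH_M)
  lower <- 100 + .BAND_DEPTH_M * idx
  lower[height_m < 100 | height_m >= 2100] <- NA_real_
  lower
}

#' Beam-axis height under the 4/3 effective-earth-radius model
#'
#' Height of the beam axis above sea level (via the antenna altitude) for a
#' given slant range and elevation, using standard-refraction propagation:
#' h = sqrt(r^2 + R'^2 + 2 r R' sin(theta)) - R' + antenna_altitude with
#' R' = (4/3) x 6371 km.
#'
#' @param range_km Slant range(s) in km (>= 0).
#' @param elevation_deg Elevation angle(s) in degrees, in [0, 90).
#' @param antenna_altitude Antenna altitude in metres (added to the result).
#' @return Beam-axis height(s) in metres.
#' @export
beam_height <- function(range_km, elevation_deg, antenna_altitude = 0) {
  if (any(range_km < 0)) stop("range must be non-negative")
  if (any(elevation_deg < 0) || any(elevation_deg >= 90)) {
    stop("elevation must be in [0, 90) degrees")
  }
  re <- .EFFECTIVE_EARTH_RADIUS_KM
  th <- elevation_deg * pi / 180
  h_km <- sqrt(range_km^2 + re^2 + 2 * range_km * re * sin(th)) - re
  h_km * 1000 + antenna_altitude
}

#' Ground-projected position of a range gate
#'
#' Projects a (elevation, azimuth, range) gate to local easting/northing in km
#' (azimuth clockwise from north) using the flat projection
#' g = r cos(elevation), and computes its beam-axis height.
#'
#' @param site A `radar_site`.
#' @param elevation_deg Elevation angle in degrees.
#' @param azimuth_deg Azimuth in degrees, [0, 360).
#' @param range_km Slant range in km, <= `site$max_range`.
#' @return A list with `easting`, `northing` (km from radar), `height`
#'   (m above the radar ground reference), plus the inputs.
#' @export
gate_ground_position <- function(site, elevation_deg, azimuth_deg, range_km) {
  if (any(azimuth_deg < 0) || any(azimuth_deg >= 360)) {
    stop("azimuth must be in [0, 360) degrees")
  }
  if (any(range_km > site$max_range)) stop("range exceeds site max_range")
  g <- range_km * cos(elevation_deg * pi / 180)
  az <- azimuth_deg * pi / 180
  list(elevation = elevation_deg, azimuth = azimuth_deg, range = range_km,
       easting = g * sin(az), northing = g * cos(az),
       height = beam_height(range_km, elevation_deg, 0))
}

#' Build the 12 x 12 CVP lattice around a radar
#'
#' Constructs the 144-cell lattice of 2.5 km-radius columns on 5 km spacing in
#' a 60 x 60 km box centred on the radar. Row 0 is northernmost, column 0
#' westernmost. The 4 x 4 central block (|easting| and |northing| <= 7.5 km)
#' is marked `central_clutter`; the upper-right corner cell (maximal easting
#' and northing) is marked `corner_unprocessed`; the remaining 127 cells are
#' `retained`.
#'
#' @param site A `radar_site`.
#' @return A `cvp_lattice`: data frame of 144 cells with `cell_id`,
#'   `grid_row`, `grid_col`, `easting_km`, `northing_km`, `radius_km`,
#'   `status`, carrying the site as an attribute.
#' @export
build_cvp_lattice <- function(site) {
  stopifnot(inherits(site, "radar_site"))
  n <- .CVP_GRID_DIM
  grid <- expand.grid(grid_col = 0:(n - 1), grid_row = 0:(n - 1))
  half <- (n - 1) / 2 * .CVP_SPACING_KM # 27.5
  easting <- -half + .CVP_SPACING_KM * grid$grid_col
  northing <- half - .CVP_SPACING_KM * grid$grid_row
  status <- rep("retained", n * n)
  status[abs(easting) <= 7.5 & abs(northing) <= 7.5] <- "central_clutter"
  status[easting == half & northing == half] <- "corner_unprocessed"
  cells <- data.frame(
    site_id = site$site_id,
    cell_id = sprintf("r%02dc%02d", grid$grid_row, grid$grid_col),
    grid_row = grid$grid_row, grid_col = grid$grid_col,
    easting_km = easting, northing_km = northing,
    radius_km = .CVP_RADIUS_KM, status = status,
    stringsAsFactors = FALSE)
  structure(cells, class = c("cvp_lattice", "data.frame"), site = site)
}

#' @export
print.cvp_lattice <- function(x, ...) {
  cat("CVP lattice for site <", attr(x, "site")$site_id, ">: ",
      nrow(x), " cells\n", sep = "")
  print(table(x$status))
  invisible(x)
}

#' Retained cells of a lattice
#' @param lattice A `cvp_lattice`.
#' @return The subset of rows with status `retained`.
#' @export
retained_cells <- function(lattice) {
  lattice[lattice$status == "retained", , drop = FALSE]
}

#' Assign radar gates to lattice columns and height bands
#'
#' Enumerates every gate of a site's scan pattern (gate centres in elevation,
#' azimuth and range), projects it to the ground, and maps it to the retained
#' column whose centre lies within 2.5 km (columns are tangent on the 5 km
#' grid, so at most one qualifies; exact boundary ties go to the nearest
#' centre, then lowest (row, col)) and to the height band containing its
#' beam-axis height. Gates outside every retained column or the 100-2100 m
#' band stack are dropped.
#'
#' @param lattice A `cvp_lattice`.
#' @param site A `radar_site` (defaults to the lattice's site).
#' @return A `gate_map`: data frame with `sweep` (elevation index), `iaz`,
#'   `irange` (1-based gate indices), `elevation`, `azimuth`, `range_km`,
#'   `height_m`, `cell_id`, `band_lower`; attribute `counts` holds the
#'   per-(cell, band) gate counts.
#' @export
assign_gates_to_columns <- function(lattice, site = attr(lattice, "site")) {
  stopifnot(inherits(lattice, "cvp_lattice"))
  ret <- retained_cells(lattice)
  half <- (.CVP_GRID_DIM - 1) / 2 * .CVP_SPACING_KM
  n_rng <- floor(site$max_range * 1000 / site$gate_length)
  rng <- (seq_len(n_rng) - 0.5) * site$gate_length / 1000   # centre, km
  az <- seq(0, 360 - site$azimuth_step, by = site$azimuth_step) +
    site$azimuth_step / 2
  out <- vector("list", length(site$elevation_angles))
  retained_key <- paste(ret$grid_row, ret$grid_col)
  for (k in seq_along(site$elevation_angles)) {
    el <- site$elevation_angles[k]
    g <- outer(rep(1, length(az)), rng * cos(el * pi / 180))  # naz x nrng
    e <- g * sin(az * pi / 180)
    n <- g * cos(az * pi / 180)
    h <- outer(rep(1, length(az)), beam_height(rng, el, 0))
    # nearest lattice centre by grid arithmetic
    col <- round((e + half) / .CVP_SPACING_KM)
    row <- round((half - n) / .CVP_SPACING_KM)
    ok <- col >= 0 & col < .CVP_GRID_DIM & row >= 0 & row < .CVP_GRID_DIM
    ce <- -half + .CVP_SPACING_KM * col
    cn <- half - .CVP_SPACING_KM * row
    d2 <- (e - ce)^2 + (n - cn)^2
    ok <- ok & d2 <= .CVP_RADIUS_KM^2
    band <- height_band_of(h)
    ok <- ok & !is.na(band)
    ok <- ok & paste(row, col) %in% retained_key
    if (!any(ok)) next
    idx <- which(ok, arr.ind = TRUE)
    out[[k]] <- data.frame(
      sweep = k, iaz = idx[, 1], irange = idx[, 2],
      elevation = el, azimuth = az[idx[, 1]], range_km = rng[idx[, 2]],
      height_m = h[ok],
      cell_id = sprintf("r%02dc%02d", row[ok], col[ok]),
      band_lower = band[ok], stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(map)) map <- data.frame()
  counts <- as.data.frame(table(cell_id = map$cell_id,
                                band_lower = map$band_lower),
                          stringsAsFactors = FALSE)
  counts$band_lower <- as.numeric(counts$band_lower)
  names(counts)[3] <- "n_gates"
  structure(map, class = c("gate_map", "data.frame"),
            counts = counts, site = site)
}

#' Mask terrain-blocked columns
#'
#' Marches the lowest-elevation beam axis from the radar towards each retained
#' column centre, sampling terrain at most every gate length; a column whose
#' ray meets terrain at or above the beam-axis height (both in m ASL) is
#' marked `terrain_blocked`.
#'
#' @param lattice A `cvp_lattice`.
#' @param terrain A `grid_raster` of terrain height in m ASL covering the
#'   60 x 60 km box.
#' @param site A `radar_site`.
#' @return The lattice with blocked cells restatused; attribute `blockage`
#'   records, per retained cell, the ray sample where blockage first occurred
#'   (NA if clear).
#' @export
terrain_mask <- function(lattice, terrain, site = attr(lattice, "site")) {
  stopifnot(inherits(lattice, "cvp_lattice"), inherits(terrain, "grid_raster"))
  half <- (.CVP_GRID_DIM - 1) / 2 * .CVP_SPACING_KM + .CVP_RADIUS_KM
  if (terrain$xmin > -half || terrain$ymin > -half ||
      terrain$xmin + terrain$cellsize * ncol(terrain$values) < half ||
      terrain$ymin + terrain$cellsize * nrow(terrain$values) < half) {
    stop("terrain raster does not cover the 60 x 60 km lattice box")
  }
  el0 <- min(site$elevation_angles)
  step <- site$gate_length / 1000
  ret_idx <- which(lattice$status == "retained")
  first_block <- rep(NA_real_, length(ret_idx))
  for (j in seq_along(ret_idx)) {
    i <- ret_idx[j]
    e <- lattice$easting_km[i]; n <- lattice$northing_km[i]
    dist <- sqrt(e^2 + n^2)
    s <- seq(step, dist, by = step)
    if (!length(s)) next
    beam_asl <- beam_height(s, el0, site$antenna_altitude)
    terr <- raster_sample(terrain, e * s / dist, n * s / dist)
    hit <- which(!is.na(terr) & terr >= beam_asl)
    if (length(hit)) {
      lattice$status[i] <- "terrain_blocked"
      first_block[j] <- s[hit[1]]
    }
  }
  attr(lattice, "blockage") <- data.frame(
    cell_id = lattice$cell_id[ret_idx],
    first_block_km = first_block, stringsAsFactors = FALSE)
  lattice
}

#' Export a lattice as CSV
#'
#' Writes site id, grid indices, local offsets, approximate longitude/latitude
#' of each cell centre and its status.
#'
#' @param lattice A `cvp_lattice`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lattice_csv <- function(lattice, path) {
  site <- attr(lattice, "site")
  # local equirectangular offsets around the site
  lat <- site$latitude + lattice$northing_km / 111.32
  lon <- site$longitude +
    lattice$easting_km / (111.32 * cos(site$latitude * pi / 180))
  out <- data.frame(site_id = lattice$site_id, grid_row = lattice$grid_row,
                    grid_col = lattice$grid_col,
                    easting_km = lattice$easting_km,
                    northing_km = lattice$northing_km,
                    lat = lat, lon = lon, status = lattice$status)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
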