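# Polar volume container: one scan time, one sweep per elevation, gate-wise
# matrices of the polarimetric moments (azimuth x range).

#' Construct a polar volume
#'
#' One radar volume scan: per elevation sweep, azimuth x range matrices of
#' reflectivity factor `Z` (dBZ), differential reflectivity `ZDR` (dB) and
#' co-polar correlation `RHOHV` (unitless). `NA` marks gates without signal.
#' Sweeps may carry an integer `CLASS` matrix (synthetic truth or filter
#' labels).
#'
#' @param site A `radar_site`.
#' @param timestamp A `POSIXct` scan time.
#' @param sweeps List (one per elevation, in `site$elevation_angles` order) of
#'   lists with elements `elevation`, `Z`, `ZDR`, `RHOHV`, optionally `CLASS`.
#' @return An object of class `polar_volume`.
#' @export
polar_volume <- function(site, timestamp, sweeps) {
  stopifnot(inherits(site, "radar_site"), length(sweeps) >= 1)
  for (sw in sweeps) {
    if (!all(c("elevation", "Z", "ZDR", "RHOHV") %in% names(sw))) {
      stop("each sweep needs elevation, Z, ZDR, RHOHV", call. = FALSE)
    }
    if (!identical(dim(sw$Z), dim(sw$ZDR)) ||
        !identical(dim(sw$Z), dim(sw$RHOHV))) {
      stop("moment matrices must share dimensions", call. = FALSE)
    }
  }
  structure(list(site = site, timestamp = as.POSIXct(timestamp, tz = "UTC"),
                 sweeps = sweeps),
            class = "polar_volume")
}

#' @export
print.polar_volume <- function(x, ...) {
  dims <- vapply(x$sweeps, function(s) paste(dim(s$Z), collapse = "x"), "")
  cat("Polar volume <", x$site$site_id, "> at ",
      format(x$timestamp, "%Y-%m-%d %H:%M:%S %Z"), "\n", sep = "")
  cat("  sweeps:", paste0(vapply(x$sweeps, `[[`, 0, "elevation"), "deg[",
                          dims, "]", collapse = " "), "\n")
  invisible(x)
}

#' Total and non-missing gate counts of a volume
#' @param volume A `polar_volume`.
#' @return Named vector with `total` and `detected` gate counts.
#' @export
gate_counts <- function(volume) {
  total <- sum(vapply(volume$sweeps, function(s) length(s$Z), 0))
  detected <- sum(vapply(volume$sweeps, function(s) sum(!is.na(s$Z)), 0))
  c(total = total, detected = detected)
}

#' Write a polar volume as long-format CSV
#'
#' Plain-text serialization: one row per non-missing gate with sweep indices,
#' gate geometry indices and the three moments (plus `CLASS` when present).
#' A `#`-prefixed header records the site geometry and timestamp.
#'
#' @param volume A `polar_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_volume_csv <- function(volume, path) {
  site <- volume$site
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# radarcvp polar volume | site=%s | time=%s | elevations=%s | gate_length=%d | azimuth_step=%g | max_range=%g | antenna_altitude=%g | wavelength=%g",
    site$site_id, format(volume$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
    paste(site$elevation_angles, collapse = ";"), site$gate_length,
    site$azimuth_step, site$max_range, site$antenna_altitude,
    site$wavelength), con)
  rows <- lapply(seq_along(volume$sweeps), function(k) {
    sw <- volume$sweeps[[k]]
    ok <- which(!is.na(sw$Z), arr.ind = TRUE)
    if (!nrow(ok)) return(NULL)
    d <- data.frame(sweep = k, iaz = ok[, 1], irange = ok[, 2],
                    Z = sw$Z[ok], ZDR = sw$ZDR[ok], RHOHV = sw$RHOHV[ok])
    d$CLASS <- if (!is.null(sw$CLASS)) sw$CLASS[ok] else NA_integer_
    d
  })
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) {
    tab <- data.frame(sweep = integer(), iaz = integer(), irange = integer(),
                      Z = numeric(), ZDR = numeric(), RHOHV = numeric(),
                      CLASS = integer())
  }
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read a polar volume written by [write_volume_csv()]
#'
#' @param path File path.
#' @return A `polar_volume` (site geometry reconstructed from the header;
#'   site coordinates default as no projection metadata is serialized).
#' @export
read_volume_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  fields <- strsplit(sub("^# radarcvp polar volume \\| ", "", hdr),
                     " \\| ")[[1]]
  kv <- strsplit(fields, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  site <- radar_site(
    site_id = vals[["site"]],
    antenna_altitude = as.numeric(vals[["antenna_altitude"]]),
    wavelength = as.numeric(vals[["wavelength"]]),
    elevation_angles = as.numeric(strsplit(vals[["elevations"]], ";")[[1]]),
    gate_length = as.numeric(vals[["gate_length"]]),
    azimuth_step = as.numeric(vals[["azimuth_step"]]),
    max_range = as.numeric(vals[["max_range"]]))
  tab <- utils::read.csv(path, skip = 1)
  naz <- 360 / site$azimuth_step
  nrng <- floor(site$max_range * 1000 / site$gate_length)
  sweeps <- lapply(seq_along(site$elevation_angles), function(k) {
    m <- function() matrix(NA_real_, naz, nrng)
    sw <- list(elevation = site$elevation_angles[k],
               Z = m(), ZDR = m(), RHOHV = m(),
               CLASS = matrix(NA_integer_, naz, nrng))
    rows <- tab[tab$sweep == k, , drop = FALSE]
    if (nrow(rows)) {
      ij <- cbind(rows$iaz, rows$irange)
      sw$Z[ij] <- rows$Z; sw$ZDR[ij] <- rows$ZDR; sw$RHOHV[ij] <- rows$RHOHV
      sw$CLASS[ij] <- rows$CLASS
    }
    sw
  })
  polar_volume(site, as.POSIXct(vals[["time"]], tz = "UTC",
                                format = "%Y-%m-%dT%H:%M:%SZ"), sweeps)
}
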