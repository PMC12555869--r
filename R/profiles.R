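# Columnar vertical profiles: azimuthal averaging of gates into
# per-(column, band) means for each scan.

#' Build columnar vertical profiles for one scan
#'
#' Averages the gates assigned to each retained (column, band) pair:
#' reflectivity factor in linear units (mm^6 m^-3, reconverted to dBZ),
#' differential reflectivity arithmetically in dB, rho_HV in natural units.
#' Bands whose non-missing gate count falls below `min_gates` are marked
#' invalid and carry no values.
#'
#' Pass a raw volume to profile every detected echo (the basis of the Z_DR
#' activity series) or a [filter_volume()] output to profile arthropod gates
#' only (the basis of abundance estimation).
#'
#' @param volume A `polar_volume`.
#' @param mapping A `gate_map` from [assign_gates_to_columns()].
#' @param min_gates Minimum non-missing gates for a valid band (default 3;
#'   set 1 for a literal single-gate reading).
#' @return A `cvp_profile` data frame: one row per (cell, band) with
#'   `timestamp`, `cell_id`, `band_lower`, `mean_z` (dBZ), `mean_zdr` (dB),
#'   `mean_rhohv`, `gate_count` (geometric), `echo_gate_count` (non-missing)
#'   and `band_valid`.
#' @export
build_profile <- function(volume, mapping, min_gates = 3) {
  stopifnot(inherits(volume, "polar_volume"), min_gates >= 1)
  key <- interaction(mapping$cell_id, mapping$band_lower, drop = TRUE)
  z <- zdr <- rho <- rep(NA_real_, nrow(mapping))
  for (k in unique(mapping$sweep)) {
    rows <- which(mapping$sweep == k)
    ij <- cbind(mapping$iaz[rows], mapping$irange[rows])
    sw <- volume$sweeps[[k]]
    z[rows] <- sw$Z[ij]; zdr[rows] <- sw$ZDR[ij]; rho[rows] <- sw$RHOHV[ij]
  }
  ok <- !is.na(z)
  n_echo <- as.numeric(tapply(ok, key, sum))
  lin_z <- 10^(z / 10)
  agg <- function(v) as.numeric(tapply(ifelse(ok, v, NA), key,
                                       mean, na.rm = TRUE))
  lev <- levels(key)
  split_lev <- strsplit(lev, ".", fixed = TRUE)
  out <- data.frame(
    site_id = volume$site$site_id,
    timestamp = volume$timestamp,
    cell_id = vapply(split_lev, `[`, "", 1),
    band_lower = as.numeric(vapply(split_lev, `[`, "", 2)),
    mean_z = 10 * log10(agg(lin_z)),
    mean_zdr = agg(zdr),
    mean_rhohv = agg(rho),
    gate_count = as.numeric(tapply(ok, key, length)),
    echo_gate_count = n_echo,
    stringsAsFactors = FALSE)
  out$band_valid <- out$echo_gate_count >= min_gates
  out$mean_z[!out$band_valid] <- NA_real_
  out$mean_zdr[!out$band_valid] <- NA_real_
  out$mean_rhohv[!out$band_valid] <- NA_real_
  out <- out[order(out$cell_id, out$band_lower), ]
  rownames(out) <- NULL
  class(out) <- c("cvp_profile", "data.frame")
  out
}

#' Profile a chronological archive of volumes
#'
#' Applies [build_profile()] to each volume and stacks the valid bands into a
#' long table keyed by (cell, band, timestamp).
#'
#' @param volumes List of `polar_volume`s in chronological order.
#' @param mapping A `gate_map`.
#' @param min_gates Passed to [build_profile()].
#' @param keep_invalid Keep invalid-band rows (default FALSE).
#' @return A `cvp_profile` data frame of all (cell, band, timestamp) rows.
#' @export
profile_series <- function(volumes, mapping, min_gates = 3,
                           keep_invalid = FALSE) {
  stamps <- as.numeric(vapply(volumes, function(v) as.numeric(v$timestamp), 0))
  if (anyDuplicated(stamps)) stop("duplicate timestamps in volume archive")
  if (is.unsorted(stamps)) stop("volumes must be chronologically ordered")
  parts <- lapply(volumes, build_profile, mapping = mapping,
                  min_gates = min_gates)
  out <- do.call(rbind, parts)
  if (!keep_invalid) out <- out[out$band_valid, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cvp_profile", "data.frame")
  out
}

#' Write a profile table as CSV
#' @param profiles A `cvp_profile` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profiles, path) {
  out <- profiles
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
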