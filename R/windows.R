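# Seasonal and diel activity windows from Z_DR series, and per-window scan
# selection.

#' Pool a profile table into a Z_DR activity series
#'
#' Averages the band mean Z_DR of all detected echoes (profiles built from
#' raw, unfiltered volumes) across cells, per scan, at one target band. The
#' diel/seasonal activity signal lives in this all-echo mean: when arthropods
#' are airborne the band mixture shifts towards their high Z_DR.
#'
#' @param profiles A `cvp_profile` table built from raw volumes.
#' @param band Target band lower edge in m (default 500).
#' @param by `"hour"` for a diel series (fractional hours UTC) or `"doy"` for
#'   a seasonal series (day of year).
#' @return Data frame with `time` and `zdr` (one row per scan).
#' @export
activity_series <- function(profiles, band = 500, by = c("hour", "doy")) {
  by <- match.arg(by)
  p <- profiles[profiles$band_lower == band & profiles$band_valid, ,
                drop = FALSE]
  if (!nrow(p)) stop("no valid profiles at band ", band)
  zdr <- tapply(p$mean_zdr, as.numeric(p$timestamp), mean, na.rm = TRUE)
  stamp <- as.POSIXct(as.numeric(names(zdr)), origin = "1970-01-01",
                      tz = "UTC")
  tvar <- if (by == "hour") {
    as.numeric(format(stamp, "%H")) + as.numeric(format(stamp, "%M")) / 60
  } else {
    as.numeric(format(stamp, "%j"))
  }
  data.frame(time = tvar, zdr = as.numeric(zdr))
}

#' Fit a cyclic smooth to a Z_DR activity series
#'
#' Penalized cyclic regression spline (GCV-selected smoothness) of mean Z_DR
#' against hour of day or day of year, evaluated on a fine grid.
#'
#' @param series Data frame with `time` and `zdr`.
#' @param kind `"diel"` (period 24 h, basis dimension 10) or `"seasonal"`
#'   (period 366 d, basis dimension 20).
#' @param k Basis dimension override.
#' @return An `activity_curve`: list with `kind`, `grid`, `fitted`, `maxima`
#'   (grid positions of local maxima of the fitted curve) and the `gam` fit.
#'   A flat (degenerate) series yields zero maxima.
#' @export
fit_activity_smooth <- function(series, kind = c("diel", "seasonal"),
                                k = NULL) {
  kind <- match.arg(kind)
  if (nrow(series) < 20) stop("need at least 20 points")
  period <- if (kind == "diel") 24 else 366
  if (is.null(k)) k <- if (kind == "diel") 10 else 20
  k <- min(k, max(4, nrow(series) - 2))
  dat <- data.frame(t = series$time, y = series$zdr)
  fit <- mgcv::gam(y ~ s(t, bs = "cc", k = k), data = dat,
                   knots = list(t = c(0, period)), method = "GCV.Cp")
  grid <- seq(0, period, length.out = 481)[-481]
  fv <- as.numeric(stats::predict(fit, data.frame(t = grid)))
  # local maxima on the cyclic grid
  n <- length(fv)
  left <- fv[c(n, seq_len(n - 1))]
  right <- fv[c(seq_len(n - 1) + 1, 1)]
  is_max <- fv > left & fv >= right
  if (diff(range(fv)) < 1e-8) is_max[] <- FALSE  # degenerate flat fit
  structure(list(kind = kind, period = period, grid = grid, fitted = fv,
                 maxima = grid[is_max], fit = fit,
                 k = k, sp = fit$sp),
            class = "activity_curve")
}

#' Extract high-activity windows from a fitted curve
#'
#' Windows are the contiguous regions (one per local maximum) where the
#' fitted curve stays at or above `frac` of its peak height above baseline
#' (baseline = fitted minimum). Bounds are rounded outward to whole hours or
#' days. Also accepts a plain `list(grid, fitted)` curve for testing against
#' constructed shapes.
#'
#' @param curve An `activity_curve` (or list with `grid`, `fitted`, and
#'   optionally `period`, `kind`).
#' @param frac Fraction of peak-above-baseline (default 0.5).
#' @return Data frame of windows: `kind`, `start`, `end` (hours or day of
#'   year). Empty when the curve has no maxima.
#' @export
extract_peak_windows <- function(curve, frac = 0.5) {
  grid <- curve$grid
  fv <- curve$fitted
  kind <- if (!is.null(curve$kind)) curve$kind else "diel"
  period <- if (!is.null(curve$period)) curve$period else max(grid)
  base <- min(fv)
  peak <- max(fv)
  empty <- data.frame(kind = character(), start = numeric(), end = numeric())
  if (peak - base < 1e-8) return(empty)
  thr <- base + frac * (peak - base)
  above <- fv >= thr
  if (!any(above)) return(empty)
  if (all(above)) {
    return(data.frame(kind = kind, start = 0, end = period))
  }
  # work in coordinates rotated to start at the global minimum so that no
  # above-threshold run straddles the cyclic seam
  rot <- grid[which.min(fv)]
  u <- (grid - rot) %% period
  ord <- order(u)
  ab <- above[ord]
  r <- rle(ab)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  rows <- lapply(which(r$values), function(i) {
    uu <- u[ord][starts[i]:ends[i]]
    s <- floor(rot + min(uu))
    e <- ceiling(rot + max(uu))
    # map back into the original cycle; a window crossing the cyclic seam is
    # reported with start > end (wrapping convention)
    if (s >= period) { s <- s - period; e <- e - period }
    if (e > period) e <- e - period
    data.frame(kind = kind, start = s, end = e)
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Operational window presets
#'
#' The fixed windows used operationally for the UK network: diel 08-14 h and
#' 18-22 h GMT (diurnal and nocturnal-including-dusk), season 15 April to
#' 30 October (days of year 105-303).
#'
#' @return List with `diel` and `seasonal` window data frames.
#' @export
preset_windows <- function() {
  list(diel = data.frame(kind = "diel", window = c("diurnal", "nocturnal"),
                         start = c(8, 18), end = c(14, 22)),
       seasonal = data.frame(kind = "seasonal", start = 105, end = 303))
}

#' Select one scan per cell, day and window
#'
#' Within each window of each day, picks for every cell the scan whose target
#' band mean Z_DR is maximal (ties broken by earliest timestamp). Selecting a
#' single per-window scan avoids double-counting individuals making repeated
#' flights.
#'
#' @param profiles A `cvp_profile` table (use raw-volume profiles so the Z_DR
#'   activity signal drives the choice).
#' @param windows Diel window data frame with `window`, `start`, `end`
#'   (hours; `start` inclusive, `end` exclusive).
#' @param band Target band lower edge (default 500 m).
#' @return Data frame with `cell_id`, `date`, `window`, `timestamp`,
#'   `mean_zdr`; cells/days with no valid scan in a window are absent.
#' @export
select_scan_per_window <- function(profiles, windows, band = 500) {
  p <- profiles[profiles$band_lower == band & profiles$band_valid &
                  is.finite(profiles$mean_zdr), , drop = FALSE]
  if (!nrow(p)) {
    return(data.frame(cell_id = character(), date = as.Date(character()),
                      window = character(), timestamp = as.POSIXct(character()),
                      mean_zdr = numeric()))
  }
  hour <- as.numeric(format(p$timestamp, "%H")) +
    as.numeric(format(p$timestamp, "%M")) / 60
  date <- as.Date(p$timestamp, tz = "UTC")
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    w <- windows[i, ]
    sel <- p[hour >= w$start & hour < w$end, , drop = FALSE]
    if (!nrow(sel)) return(NULL)
    sel$date <- date[hour >= w$start & hour < w$end]
    sel <- sel[order(sel$cell_id, sel$date, -sel$mean_zdr, sel$timestamp), ]
    first <- !duplicated(sel[, c("cell_id", "date")])
    data.frame(cell_id = sel$cell_id[first], date = sel$date[first],
               window = as.character(w$window), timestamp = sel$timestamp[first],
               mean_zdr = sel$mean_zdr[first], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame(cell_id = character(),
                                      date = as.Date(character()),
                                      window = character(),
                                      timestamp = as.POSIXct(character()),
                                      mean_zdr = numeric())
  rownames(out) <- NULL
  out
}

#' Write windows as CSV
#' @param windows A window data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_windows_csv <- function(windows, path) {
  utils::write.csv(windows, path, row.names = FALSE)
  invisible(path)
}
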