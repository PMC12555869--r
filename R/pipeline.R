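# End-to-end orchestration: geometry -> simulate/ingest -> classify ->
# profiles -> windows -> abundance -> trend, with a provenance manifest and
# deterministic reruns.

#' Default pipeline run configuration
#'
#' Collects every threshold, constant and seed of a run. All values are
#' echoed into the output manifest so a run is auditable and exactly
#' repeatable.
#'
#' @param out_dir Output directory.
#' @param seed Base seed (drives the synthetic scene when simulating).
#' @param simulate Generate a synthetic study (the only input mode bundled
#'   with the package; real-volume ingest plugs in via `volumes`).
#' @param volumes Optional list of `polar_volume`s when not simulating.
#' @param site A `radar_site`.
#' @param sigma Mean radar cross-section in cm^2 (required for abundance).
#' @param beta Reflectivity offset in dB (or `NULL` with `wavelength` set).
#' @param wavelength Wavelength (cm) to compute beta from when `beta` is
#'   `NULL`.
#' @param band Target analysis band lower edge (m).
#' @param windows `"preset"` for the operational diel windows or `"fit"` to
#'   fit them from the Z_DR activity series.
#' @param filter A [filter_config()].
#' @param min_gates Valid-band gate threshold.
#' @param scene A [scene_config()] for simulation (default built from
#'   `seed`).
#' @param dates Dates simulated/processed.
#' @param hours Scanned hours per day.
#' @param scan_interval_min Minutes between volumes.
#' @param terrain Optional terrain `grid_raster` for blockage masking.
#' @param covariates Optional named list of covariate `grid_raster`s for the
#'   trend stage.
#' @param fit_trend Fit the trend model stage (needs enough dates/years).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, simulate = TRUE, volumes = NULL,
                       site = radar_site(), sigma = 1, beta = 26.58,
                       wavelength = NULL, band = 500,
                       windows = c("preset", "fit"),
                       filter = filter_config(), min_gates = 3,
                       scene = NULL, dates = as.Date("2021-07-01"),
                       hours = c(6, 23), scan_interval_min = 60,
                       terrain = NULL, covariates = NULL,
                       fit_trend = FALSE) {
  windows <- match.arg(windows)
  if (is.null(scene)) scene <- scene_config(seed = seed)
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 volumes = volumes, site = site, sigma = sigma, beta = beta,
                 wavelength = wavelength, band = band, windows = windows,
                 filter = filter, min_gates = min_gates, scene = scene,
                 dates = as.Date(dates), hours = hours,
                 scan_interval_min = scan_interval_min, terrain = terrain,
                 covariates = covariates, fit_trend = fit_trend),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order: geometry (lattice + gate assignment +
#' optional terrain masking) -> scene simulation or volume ingest ->
#' per-gate classification -> CVP profiles -> window selection -> abundance
#' conversion -> optional trend modelling. Stage artifacts are written to
#' `config$out_dir` as CSV and a JSON manifest records config, seeds and
#' file checksums; a failing stage stops with a stage-named error, leaving
#' earlier artifacts in place.
#'
#' @param config A [run_config()].
#' @return Invisible list of stage outputs (`lattice`, `mapping`, `study` or
#'   `profiles`, `windows`, `selection`, `estimates`, `trend`, `manifest`).
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  emit <- function(writer, obj, file, ...) {
    path <- file.path(config$out_dir, file)
    writer(obj, path, ...)
    artifacts[[length(artifacts) + 1]] <<- path
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  out <- list()

  out$lattice <- stage("geometry", {
    lat <- build_cvp_lattice(config$site)
    if (!is.null(config$terrain)) {
      lat <- terrain_mask(lat, config$terrain, config$site)
    }
    lat
  })
  emit(write_lattice_csv, out$lattice, "lattice.csv")
  out$mapping <- stage("geometry",
                       assign_gates_to_columns(out$lattice, config$site))

  if (config$simulate) {
    out$study <- stage("simulate", simulate_study(
      config$scene, config$site, out$lattice, config$dates,
      hours = config$hours, scan_interval_min = config$scan_interval_min,
      filter_cfg = config$filter, min_gates = config$min_gates,
      mapping = out$mapping))
    profiles_raw <- out$study$profiles_raw
    profiles_filtered <- out$study$profiles_filtered
    label_counts <- out$study$label_counts
    emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
         data.frame(label = names(label_counts),
                    count = as.numeric(label_counts)),
         "classification_counts.csv")
  } else {
    if (is.null(config$volumes)) stop("pipeline stage 'ingest' failed: no volumes supplied and simulate = FALSE")
    filtered <- stage("classify", lapply(config$volumes, filter_volume,
                                         cfg = config$filter))
    profiles_raw <- stage("profiles", profile_series(
      config$volumes, out$mapping, min_gates = config$min_gates))
    profiles_filtered <- stage("profiles", profile_series(
      filtered, out$mapping, min_gates = config$min_gates))
    label_counts <- Reduce(`+`, lapply(filtered, attr, "label_counts"))
  }
  emit(write_profile_csv, profiles_raw, "profiles_raw.csv")
  emit(write_profile_csv, profiles_filtered, "profiles_filtered.csv")

  out$windows <- stage("windows", {
    if (config$windows == "preset") preset_windows()$diel else {
      series <- activity_series(profiles_raw, band = config$band,
                                by = "hour")
      curve <- fit_activity_smooth(series, kind = "diel")
      w <- extract_peak_windows(curve)
      if (!nrow(w)) stop("no activity windows found")
      w$window <- if (nrow(w) >= 2) {
        c("diurnal", "nocturnal", paste0("extra", seq_len(nrow(w) - 2) + 2))[
          seq_len(nrow(w))]
      } else "diurnal"
      w
    }
  })
  emit(write_windows_csv, out$windows, "windows.csv")

  out$selection <- stage("windows", select_scan_per_window(
    profiles_raw, out$windows, band = config$band))
  emit(function(o, p) utils::write.csv(o, p, row.names = FALSE),
       out$selection, "scan_selection.csv")

  constants <- stage("abundance", radar_constants(
    sigma = config$sigma, beta = config$beta,
    wavelength = config$wavelength))
  out$constants <- constants
  out$estimates <- stage("abundance", abundance_estimates(
    profiles_filtered, out$selection, constants))
  emit(write_abundance_csv, out$estimates, "estimates.csv",
       constants = constants)

  if (!nrow(out$estimates)) {
    message("no abundance estimates (empty scene?); trend stage skipped")
  } else if (config$fit_trend && !is.null(config$covariates) &&
             length(unique(format(out$estimates$date, "%Y"))) >= 2) {
    out$trend <- stage("trend", {
      tab <- assemble_model_table(out$estimates, config$covariates,
                                  out$lattice, band = config$band)
      fit_trend_gam(trend_spec(list(
        term_smooth("year", k = 5), term_smooth2d(c("x", "y"), k = 30)),
        name = "pipeline"), tab)
    })
  } else if (config$fit_trend) {
    message("trend stage skipped: need covariates and >= 2 years")
  }

  manifest <- list(
    package = "radarcvp",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    seed = config$seed,
    band = config$band,
    windows_mode = config$windows,
    filter = unclass(config$filter),
    constants = list(sigma = config$sigma,
                     beta = out$constants$beta,
                     beta_source = out$constants$beta_source),
    dates = as.character(config$dates),
    stages = c("geometry", if (config$simulate) "simulate" else "ingest",
               "classify", "profiles", "windows", "abundance",
               if (!is.null(out$trend)) "trend"),
    artifacts = lapply(artifacts, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    }))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  out$manifest <- manifest
  invisible(out)
}
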