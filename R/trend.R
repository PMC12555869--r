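# Hierarchical spatio-temporal additive modelling of abundance: model table
# assembly, AR(1) rho estimation, penalized-spline fitting with double-penalty
# shrinkage selection, candidate ladder ranking, Moran's I correlograms,
# prediction surfaces and annual trends.

#' Term constructors for trend model specifications
#'
#' Build the term list of a [trend_spec()]: `term_smooth` a 1-D thin-plate
#' smooth, `term_smooth2d` an isotropic 2-D smooth (spatial f(x, y)),
#' `term_ti` a tensor-product interaction, `term_re` a random intercept,
#' `term_by_smooth` a by-factor smooth (e.g. a year smooth per radar),
#' `term_linear` a parametric term.
#'
#' @param var,vars Covariate name(s).
#' @param k Basis dimension.
#' @param by Factor name for `term_by_smooth`.
#' @return A term descriptor list.
#' @name trend_terms
NULL

#' @rdname trend_terms
#' @export
term_smooth <- function(var, k = 8) list(type = "smooth", vars = var, k = k)
#' @rdname trend_terms
#' @export
term_smooth2d <- function(vars = c("x", "y"), k = 30) {
  list(type = "smooth2d", vars = vars, k = k)
}
#' @rdname trend_terms
#' @export
term_ti <- function(vars, k = 5) list(type = "ti", vars = vars, k = k)
#' @rdname trend_terms
#' @export
term_re <- function(var) list(type = "re", vars = var)
#' @rdname trend_terms
#' @export
term_by_smooth <- function(var, by, k = 5) {
  list(type = "by_smooth", vars = var, by = by, k = k)
}
#' @rdname trend_terms
#' @export
term_linear <- function(var) list(type = "linear", vars = var)

#' Specify a spatio-temporal trend model
#'
#' Gaussian identity-link additive model of (optionally log10(x + 1)
#' transformed) abundance density with thin-plate spline smooths, random
#' intercepts and optional AR(1) errors, fitted with REML-type smoothing
#' selection and (by default) the double-penalty shrinkage that can remove a
#' covariate entirely.
#'
#' @param terms List of term descriptors (see [trend_terms]).
#' @param name Candidate label.
#' @param select Enable double-penalty shrinkage selection.
#' @param log10_response Fit log10(response + 1) (flag is recorded in the
#'   fit).
#' @return An object of class `trend_spec`.
#' @export
trend_spec <- function(terms, name = "model", select = TRUE,
                       log10_response = TRUE) {
  vars <- unlist(lapply(terms, function(t) t$vars))
  smooth_vars <- unlist(lapply(terms, function(t) {
    if (t$type %in% c("smooth", "linear")) t$vars else NULL
  }))
  if (anyDuplicated(smooth_vars)) {
    stop("a covariate may appear in at most one smooth/linear term")
  }
  structure(list(terms = terms, name = name, select = select,
                 log10_response = log10_response, vars = unique(vars)),
            class = "trend_spec")
}

.term_formula <- function(t) {
  switch(t$type,
    smooth = sprintf("s(%s, k = %d)", t$vars, t$k),
    smooth2d = sprintf("s(%s, k = %d)", paste(t$vars, collapse = ", "), t$k),
    ti = sprintf("ti(%s, k = %d)", paste(t$vars, collapse = ", "), t$k),
    re = sprintf('s(%s, bs = "re")', t$vars),
    by_smooth = sprintf('s(%s, by = %s, k = %d)', t$vars, t$by, t$k),
    linear = t$vars,
    stop("unknown term type ", t$type))
}

#' Pooled AR(1) starting value from within-series residuals
#'
#' Lag-1 autocorrelation of residuals pooled across series (within-series
#' lagged products over within-series squares), the standard starting value
#' for an AR(1) error model.
#'
#' @param residuals Residual vector, ordered in time within each series.
#' @param series Series identifier (e.g. cell id), same length.
#' @return Estimated rho.
#' @export
estimate_rho <- function(residuals, series = rep(1, length(residuals))) {
  if (stats::var(residuals, na.rm = TRUE) == 0) {
    stop("residuals have zero variance; rho undefined")
  }
  num <- den <- 0
  for (s in split(residuals, series)) {
    if (length(s) < 2) next
    a <- s[-1]; b <- s[-length(s)]
    ok <- is.finite(a) & is.finite(b)
    num <- num + sum(a[ok] * b[ok])
    den <- den + sum(b[ok]^2)
  }
  if (den == 0) stop("need at least 2 observations in some series")
  num / den
}

#' Fit a spatio-temporal trend model
#'
#' Fits the spec with `mgcv::bam` (fast REML, `select = TRUE` double-penalty
#' shrinkage when requested) and an AR(1) error model: when `rho` is `NULL`,
#' a first pass without autocorrelation supplies residuals to
#' [estimate_rho()] and the model is refitted with that rho (observations are
#' ordered in time within each series; `AR.start` marks series starts).
#' Terms whose variables are absent from the table, and random-effect or
#' by-factors with fewer than 2 levels, are dropped with a warning.
#'
#' @param spec A [trend_spec()].
#' @param table Model table (one row per cell/date/window observation).
#' @param response Response column name (default `"density"`).
#' @param series_col Series identifier column for the AR(1) ordering
#'   (default `"cell_id"`).
#' @param time_col Time-ordering column within series (default `"date"`,
#'   falling back to `"year"`).
#' @param rho AR(1) rho in [0, 1); `NULL` = estimate via a first pass; 0 =
#'   independent errors.
#' @param discrete Use `mgcv::bam`'s covariate discretization (worthwhile for
#'   very large tables; incompatible with some tensor/2-D nesting
#'   structures).
#' @return A `trend_fit`: list with the `mgcv` fit (`$fit`), `aic`,
#'   `deviance_explained`, `adj_r2`, `edf` per smooth, `rho` used,
#'   `rho_estimated` (first-pass estimate), residuals (standardized for the
#'   AR model) and the prepared data.
#' @export
fit_trend_gam <- function(spec, table, response = "density",
                          series_col = "cell_id", time_col = NULL,
                          rho = NULL, discrete = FALSE) {
  stopifnot(inherits(spec, "trend_spec"))
  if (is.null(time_col)) {
    time_col <- if ("date" %in% names(table)) "date" else "year"
  }
  dat <- as.data.frame(table)
  if (!response %in% names(dat)) stop("response column '", response,
                                      "' not in table")
  dat$.y <- if (spec$log10_response) log10(dat[[response]] + 1) else {
    dat[[response]]
  }
  # drop infeasible terms
  keep <- vapply(spec$terms, function(t) {
    vars <- c(t$vars, t$by)
    if (!all(vars %in% names(dat))) {
      warning("dropping term on '", paste(vars, collapse = ","),
              "': variable absent", call. = FALSE)
      return(FALSE)
    }
    if (t$type %in% c("re", "by_smooth")) {
      f <- if (t$type == "re") t$vars else t$by
      dat[[f]] <<- as.factor(dat[[f]])
      if (nlevels(droplevels(dat[[f]])) < 2) {
        warning("dropping term on factor '", f, "': fewer than 2 levels",
                call. = FALSE)
        return(FALSE)
      }
    }
    TRUE
  }, logical(1))
  terms <- spec$terms[keep]
  rhs <- if (length(terms)) {
    paste(vapply(terms, .term_formula, ""), collapse = " + ")
  } else "1"
  form <- stats::as.formula(paste(".y ~", rhs))
  ord <- order(dat[[series_col]], dat[[time_col]])
  dat <- dat[ord, , drop = FALSE]
  ar_start <- !duplicated(dat[[series_col]])

  has_smooth <- length(terms) > 0 &&
    any(vapply(terms, function(t) t$type != "linear", logical(1)))
  fit_once <- function(r) {
    if (!has_smooth) {
      # purely parametric model (e.g. intercept-only baseline): plain gam
      return(mgcv::gam(form, data = dat, method = "REML"))
    }
    mgcv::bam(form, data = dat, method = "fREML", select = spec$select,
              rho = r, AR.start = ar_start, discrete = discrete)
  }
  rho_est <- NA_real_
  if (is.null(rho)) {
    fit0 <- fit_once(0)
    rho_est <- estimate_rho(stats::residuals(fit0), dat[[series_col]])
    rho <- max(0, min(0.98, rho_est))
    fit <- if (rho > 0) fit_once(rho) else fit0
  } else {
    fit <- fit_once(rho)
  }
  s <- summary(fit)
  res_std <- if (rho > 0 && !is.null(fit$std.rsd)) fit$std.rsd else {
    stats::residuals(fit)
  }
  structure(list(
    fit = fit, spec = spec, formula = form,
    aic = stats::AIC(fit),
    deviance_explained = as.numeric(s$dev.expl),
    adj_r2 = as.numeric(s$r.sq),
    edf = if (length(fit$smooth)) {
      stats::setNames(s$edf, vapply(fit$smooth, function(x) x$label, ""))
    } else numeric(0),
    rho = rho, rho_estimated = rho_est,
    residuals = stats::residuals(fit),
    residuals_std = res_std,
    data = dat, response = response,
    log10_response = spec$log10_response,
    series_col = series_col, time_col = time_col),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Trend fit <", x$spec$name, ">: AIC ", round(x$aic, 1),
      ", deviance explained ", sprintf("%.1f%%", 100 * x$deviance_explained),
      ", adj-R2 ", round(x$adj_r2, 3), ", rho ", round(x$rho, 3),
      "\n", sep = "")
  if (length(x$edf)) {
    cat("  EDF:", paste(names(x$edf), round(x$edf, 2), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Default candidate ladder of trend models
#'
#' Seven nested candidates from a year-only smooth up to the full
#' spatio-temporal model with year-by-radar smooths: (1) f(year);
#' (2) + f(x, y); (3) + random intercepts (radar, month, grid cell);
#' (4) + climate smooths (Tmax, Rain, Wind); (5) + land-cover smooths
#' (arable, woodland, grassland, urban); (6) + ALAN and elevation (the full
#' model); (7) + year-by-radar smooths.
#'
#' @param k1 Basis dimension for 1-D smooths.
#' @param k2 Basis dimension for the spatial smooth.
#' @return List of seven [trend_spec()]s.
#' @export
candidate_ladder <- function(k1 = 8, k2 = 30) {
  base <- list(term_smooth("year", k = 5))
  spat <- c(base, list(term_smooth2d(c("x", "y"), k = k2)))
  ranef <- c(spat, list(term_re("radar"), term_re("month"),
                        term_re("cell_id")))
  clim <- c(ranef, list(term_smooth("tmax", k1), term_smooth("rain", k1),
                        term_smooth("wind", k1)))
  land <- c(clim, list(term_smooth("arable", k1), term_smooth("woodland", k1),
                       term_smooth("grassland", k1),
                       term_smooth("urban", k1)))
  full <- c(land, list(term_smooth("alan", k1), term_smooth("elevation", k1)))
  full_by <- c(full, list(term_by_smooth("year", by = "radar", k = 5)))
  mk <- function(t, n) trend_spec(t, name = n)
  list(mk(base, "m1_year"), mk(spat, "m2_spatial"), mk(ranef, "m3_ranef"),
       mk(clim, "m4_climate"), mk(land, "m5_landcover"), mk(full, "m6_full"),
       mk(full_by, "m7_full_byradar"))
}

#' Fit and rank candidate models
#'
#' Fits every candidate on the same table and ranks by AIC, reporting
#' delta-AIC, adjusted R^2 and deviance explained. Candidates that fail to
#' fit are recorded and excluded from the ranking. Duplicate candidates rank
#' stably by index.
#'
#' @param specs List of [trend_spec()]s.
#' @param table Model table.
#' @param ... Passed to [fit_trend_gam()] (e.g. `response`, `rho`).
#' @return List with `ranking` (data frame, best first), `fits` (named list)
#'   and `failures` (named character of error messages).
#' @export
select_best_model <- function(specs, table, ...) {
  stopifnot(length(specs) >= 2)
  names(specs) <- vapply(specs, function(s) s$name, "")
  fits <- list(); failures <- character(0)
  for (nm in names(specs)) {
    f <- tryCatch(suppressWarnings(fit_trend_gam(specs[[nm]], table, ...)),
                  error = function(e) e)
    if (inherits(f, "error")) failures[nm] <- conditionMessage(f) else {
      fits[[nm]] <- f
    }
  }
  if (!length(fits)) stop("no candidate fitted successfully")
  tab <- data.frame(
    name = names(fits),
    index = match(names(fits), names(specs)),
    aic = vapply(fits, `[[`, 0, "aic"),
    dev_expl = vapply(fits, `[[`, 0, "deviance_explained"),
    adj_r2 = vapply(fits, `[[`, 0, "adj_r2"),
    rho = vapply(fits, `[[`, 0, "rho"))
  tab <- tab[order(tab$aic, tab$index), ]
  tab$delta_aic <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  list(ranking = tab, fits = fits, failures = failures)
}

#' Moran's I correlogram with permutation test
#'
#' Moran's I of `values` at point coordinates within binary distance bands,
#' with expectation -1/(n-1) under independence and a two-sided permutation
#' p-value per band. p-values are reported unadjusted across bins.
#'
#' @param values Numeric vector (e.g. per-cell mean residuals).
#' @param x,y Coordinates (km).
#' @param breaks Distance-band breaks (km); band i is (breaks\[i\],
#'   breaks\[i+1\]\].
#' @param n_perm Number of permutations.
#' @param seed RNG seed for the permutations.
#' @param alternative `"two.sided"`, or `"greater"`/`"less"` for one-sided
#'   tests. Residual diagnostics of models containing a spatial smooth
#'   should use `"greater"` (unmodelled positive clustering): such residuals
#'   are slightly negatively autocorrelated at short range by construction,
#'   because the smooth absorbs part of the local mean.
#' @return A `moran_result` data frame: `lo`, `hi`, `n_pairs`, `observed`,
#'   `expected`, `p` (`NA` and a `flagged` marker for empty bins).
#' @export
morans_i_correlogram <- function(values, x, y,
                                 breaks = c(0, 7.5, 15, 25, 40),
                                 n_perm = 199, seed = 1,
                                 alternative = c("two.sided", "greater",
                                                 "less")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  stopifnot(n >= 10, length(x) == n, length(y) == n)
  d <- as.matrix(stats::dist(cbind(x, y)))
  set.seed(seed)
  perms <- replicate(n_perm, sample.int(n))
  moran_stat <- function(z, w, s0) {
    zc <- z - mean(z)
    n * as.numeric(zc %*% w %*% zc) / (s0 * sum(zc^2))
  }
  expected <- -1 / (n - 1)
  rows <- lapply(seq_len(length(breaks) - 1), function(i) {
    w <- (d > breaks[i] & d <= breaks[i + 1]) * 1
    diag(w) <- 0
    s0 <- sum(w)
    if (s0 == 0) {
      return(data.frame(lo = breaks[i], hi = breaks[i + 1], n_pairs = 0,
                        observed = NA_real_, expected = expected,
                        p = NA_real_, flagged = TRUE))
    }
    obs <- moran_stat(values, w, s0)
    null <- apply(perms, 2, function(p) moran_stat(values[p], w, s0))
    exceed <- switch(alternative,
      two.sided = abs(null - expected) >= abs(obs - expected),
      greater = null >= obs,
      less = null <= obs)
    p <- (1 + sum(exceed)) / (n_perm + 1)
    data.frame(lo = breaks[i], hi = breaks[i + 1], n_pairs = s0 / 2,
               observed = obs, expected = expected, p = p, flagged = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("moran_result", "data.frame")
  out
}

#' Per-cell mean residuals with coordinates
#'
#' Averages a fit's residuals by cell and attaches cell centroids, the input
#' for a residual correlogram.
#'
#' @param fit A `trend_fit`.
#' @param lattice Optional `cvp_lattice` for centroids; if absent, `x`/`y`
#'   columns of the model table are used.
#' @return Data frame with `cell_id`, `x`, `y`, `resid`.
#' @export
residual_cell_means <- function(fit, lattice = NULL) {
  dat <- fit$data
  r <- tapply(fit$residuals, dat[[fit$series_col]], mean)
  cells <- names(r)
  if (!is.null(lattice)) {
    idx <- match(cells, lattice$cell_id)
    x <- lattice$easting_km[idx]; y <- lattice$northing_km[idx]
  } else {
    x <- tapply(dat$x, dat[[fit$series_col]], mean)[cells]
    y <- tapply(dat$y, dat[[fit$series_col]], mean)[cells]
  }
  data.frame(cell_id = cells, x = as.numeric(x), y = as.numeric(y),
             resid = as.numeric(r))
}

# smooth labels of random-effect terms, to exclude at population level
.re_labels <- function(fit) {
  labs <- vapply(fit$smooth, function(s) s$label, "")
  labs[vapply(fit$smooth, function(s) inherits(s, "random.effect"),
              logical(1))]
}

#' Predict abundance surfaces from covariate rasters
#'
#' Evaluates the fitted linear predictor pixel-wise over a covariate raster
#' stack for each requested year, with standard errors from the coefficient
#' covariance (first-order Taylor/delta method). Random-effect intercepts are
#' set to the population level. Pixels with any covariate outside its
#' training range are flagged as extrapolation.
#'
#' @param fit A `trend_fit`.
#' @param rasters Named list of `grid_raster`s covering every covariate in
#'   the fit (plus implicit `x`/`y` from pixel coordinates).
#' @param years Years to predict.
#' @return List per year with `prediction`, `se`, `extrapolation`
#'   `grid_raster`s (response on the fitted, possibly log10, scale).
#' @export
predict_map <- function(fit, rasters, years) {
  r0 <- rasters[[1]]
  nr <- nrow(r0$values); nc <- ncol(r0$values)
  xc <- r0$xmin + (seq_len(nc) - 0.5) * r0$cellsize
  yc <- r0$ymin + (nr - seq_len(nr) + 0.5) * r0$cellsize
  newd <- expand.grid(x = xc, y = yc)  # column-major over x first
  # map pixel order to matrix indices: rows of newd vary x fastest
  needed <- setdiff(fit$spec$vars, c("x", "y", "year"))
  for (v in needed) {
    if (v %in% names(rasters)) {
      newd[[v]] <- raster_sample(rasters[[v]], newd$x, newd$y)
    } else if (is.factor(fit$data[[v]])) {
      newd[[v]] <- factor(levels(fit$data[[v]])[1],
                          levels = levels(fit$data[[v]]))
    } else {
      stop("no raster supplied for covariate '", v, "'")
    }
  }
  extrap <- rep(FALSE, nrow(newd))
  for (v in intersect(needed, names(rasters))) {
    rng <- range(fit$data[[v]], na.rm = TRUE)
    extrap <- extrap | is.na(newd[[v]]) | newd[[v]] < rng[1] |
      newd[[v]] > rng[2]
  }
  excl <- .re_labels(fit$fit)
  # factors must still be present in newdata even when excluded
  for (f in names(fit$data)) {
    if (is.factor(fit$data[[f]]) && !f %in% names(newd)) {
      newd[[f]] <- factor(levels(fit$data[[f]])[1],
                          levels = levels(fit$data[[f]]))
    }
  }
  out <- lapply(years, function(yr) {
    nd <- newd
    nd$year <- yr
    pr <- stats::predict(fit$fit, newdata = nd, se.fit = TRUE,
                         exclude = if (length(excl)) excl else NULL,
                         newdata.guaranteed = TRUE)
    # newd rows vary x fastest with yc ordered north to south, so the
    # byrow-filled matrix is already in map orientation
    shape <- function(v) matrix(v, nr, nc, byrow = TRUE)
    list(year = yr,
         prediction = grid_raster(shape(as.numeric(pr$fit)), r0$xmin,
                                  r0$ymin, r0$cellsize, "prediction"),
         se = grid_raster(shape(as.numeric(pr$se.fit)), r0$xmin, r0$ymin,
                          r0$cellsize, "se"),
         extrapolation = grid_raster(shape(extrap), r0$xmin, r0$ymin,
                                     r0$cellsize, "extrapolation"))
  })
  stats::setNames(out, years)
}

#' Annual mean predictions and first-to-last-year change map
#'
#' Averages model predictions over all cells per year (standard errors from
#' the coefficient covariance on the averaged linear predictor) and computes
#' the per-cell difference between the last and first year, holding each
#' cell's covariates at its observed mean (on the fitted, possibly log10,
#' scale).
#'
#' @param fit A `trend_fit`.
#' @param years Years to evaluate (default: range observed in the data).
#' @return List with `annual` (data frame `year`, `mean_prediction`, `se`)
#'   and `change` (data frame `cell_id`, `x`, `y`, `first`, `last`,
#'   `change`).
#' @export
annual_trend <- function(fit, years = NULL) {
  dat <- fit$data
  if (is.null(years)) years <- sort(unique(dat$year))
  if (length(years) < 2) stop("need at least 2 years")
  cells <- unique(dat[[fit$series_col]])
  num_vars <- setdiff(fit$spec$vars, c("year"))
  base <- data.frame(cell_id = cells, stringsAsFactors = FALSE)
  names(base)[1] <- fit$series_col
  for (v in num_vars) {
    if (!v %in% names(dat)) next
    if (is.numeric(dat[[v]])) {
      base[[v]] <- as.numeric(tapply(dat[[v]], dat[[fit$series_col]],
                                     mean)[as.character(cells)])
    } else {
      base[[v]] <- dat[[v]][match(cells, dat[[fit$series_col]])]
    }
  }
  for (f in names(dat)) {
    if (is.factor(dat[[f]]) && !f %in% names(base)) {
      base[[f]] <- dat[[f]][match(cells, dat[[fit$series_col]])]
    }
  }
  excl <- .re_labels(fit$fit)
  pred_year <- function(yr) {
    nd <- base
    nd$year <- yr
    Xp <- stats::predict(fit$fit, newdata = nd, type = "lpmatrix",
                         exclude = if (length(excl)) excl else NULL,
                         newdata.guaranteed = TRUE)
    if (length(excl)) {
      # zero the columns of excluded random-effect smooths
      for (s in fit$fit$smooth) {
        if (s$label %in% excl) Xp[, s$first.para:s$last.para] <- 0
      }
    }
    list(Xp = Xp, fit = as.numeric(Xp %*% stats::coef(fit$fit)))
  }
  Vp <- fit$fit$Vp
  annual <- do.call(rbind, lapply(years, function(yr) {
    p <- pred_year(yr)
    a <- colMeans(p$Xp)
    data.frame(year = yr, mean_prediction = mean(p$fit),
               se = sqrt(drop(t(a) %*% Vp %*% a)))
  }))
  pf <- pred_year(min(years)); pl <- pred_year(max(years))
  if (!is.null(attr(dat, "cell_coords"))) {
    cc <- attr(dat, "cell_coords")
  } else {
    cc <- data.frame(
      x = as.numeric(tapply(dat$x, dat[[fit$series_col]],
                            mean)[as.character(cells)]),
      y = as.numeric(tapply(dat$y, dat[[fit$series_col]],
                            mean)[as.character(cells)]))
  }
  change <- data.frame(cell_id = cells, x = cc$x, y = cc$y,
                       first = pf$fit, last = pl$fit,
                       change = pl$fit - pf$fit)
  list(annual = annual, change = change)
}

#' Assemble the modelling table from estimates and covariates
#'
#' One row per (cell, date, window) abundance estimate at the target band,
#' with covariates as footprint means over each cell's 2.5 km disc, cell
#' centroid coordinates, and factors (radar, month, grid cell, year).
#' Diurnal and nocturnal estimates should be modelled separately; filter with
#' `window` before or after assembly. Rows with a missing covariate are
#' dropped and counted in the `dropped` attribute.
#'
#' @param estimates An `abundance_estimate` table.
#' @param rasters Named list of covariate `grid_raster`s.
#' @param lattice The `cvp_lattice`.
#' @param band Target band lower edge (default 500 m).
#' @param window Optional window filter (`"diurnal"`/`"nocturnal"`).
#' @return Model table data frame with `density`, covariates, `x`, `y`,
#'   `radar`, `month`, `cell_id`, `year`, `date`.
#' @export
assemble_model_table <- function(estimates, rasters, lattice, band = 500,
                                 window = NULL) {
  est <- estimates[estimates$band_lower == band, , drop = FALSE]
  if (!is.null(window)) est <- est[est$window == window, , drop = FALSE]
  ret <- retained_cells(lattice)
  idx <- match(est$cell_id, ret$cell_id)
  tab <- data.frame(cell_id = est$cell_id, date = est$date,
                    window = est$window, density = est$density,
                    x = ret$easting_km[idx], y = ret$northing_km[idx],
                    radar = factor(est$site_id),
                    month = factor(format(est$date, "%m")),
                    year = as.numeric(format(est$date, "%Y")),
                    stringsAsFactors = FALSE)
  fp <- lapply(rasters, function(r) {
    vals <- vapply(seq_len(nrow(ret)), function(i) {
      footprint_mean(r, ret$easting_km[i], ret$northing_km[i],
                     ret$radius_km[i])
    }, 0)
    vals[idx]
  })
  tab <- cbind(tab, as.data.frame(fp))
  ok <- stats::complete.cases(tab)
  dropped <- sum(!ok)
  if (dropped) {
    message(dropped, " rows dropped for missing covariates")
  }
  out <- tab[ok, , drop = FALSE]
  out$cell_id <- factor(out$cell_id)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
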