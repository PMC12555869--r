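# Minimal single-band raster on a regular grid in local radar coordinates
# (km east/north of the radar), with ESRI ASCII grid text I/O.

#' Create a grid raster
#'
#' A single-band raster on a regular grid in local coordinates (km east and
#' north of the radar). Values are stored as a matrix whose first row is the
#' northernmost row (map orientation).
#'
#' @param values Numeric matrix (rows north to south).
#' @param xmin,ymin Coordinates of the lower-left corner (km).
#' @param cellsize Cell size (km).
#' @param name Optional band name.
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, xmin, ymin, cellsize, name = "band") {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(list(values = values, xmin = xmin, ymin = ymin,
                 cellsize = cellsize, name = name),
            class = "grid_raster")
}

#' @export
print.grid_raster <- function(x, ...) {
  cat("grid_raster <", x$name, ">: ", nrow(x$values), " x ", ncol(x$values),
      " cells of ", x$cellsize, " km, origin (", x$xmin, ", ", x$ymin,
      ")\n", sep = "")
  cat("  values: [", signif(min(x$values, na.rm = TRUE), 4), ", ",
      signif(max(x$values, na.rm = TRUE), 4), "]\n", sep = "")
  invisible(x)
}

#' Sample a raster at point locations
#'
#' Nearest-cell lookup; points outside the raster return `NA`.
#'
#' @param r A `grid_raster`.
#' @param x,y Coordinates (km), recycled to a common length.
#' @return Numeric vector of sampled values.
#' @export
raster_sample <- function(r, x, y) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  ci <- floor((x - r$xmin) / r$cellsize) + 1
  ri <- nr - floor((y - r$ymin) / r$cellsize)
  ok <- ci >= 1 & ci <= nc & ri >= 1 & ri <= nr
  out <- rep(NA_real_, length(ok))
  out[ok] <- r$values[cbind(ri[ok], ci[ok])]
  out
}

#' Mean raster value over a disc footprint
#'
#' Averages all cell centres within `radius` of (`x0`, `y0`); used for CVP
#' footprint means of covariate rasters.
#'
#' @param r A `grid_raster`.
#' @param x0,y0 Disc centre (km).
#' @param radius Disc radius (km).
#' @return Mean value (NA if no cell centre falls inside the disc).
#' @export
footprint_mean <- function(r, x0, y0, radius = 2.5) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  xc <- r$xmin + (seq_len(nc) - 0.5) * r$cellsize
  yc <- r$ymin + (nr - seq_len(nr) + 0.5) * r$cellsize
  dx2 <- outer(rep(1, nr), (xc - x0)^2)
  dy2 <- outer((yc - y0)^2, rep(1, nc))
  inside <- dx2 + dy2 <= radius^2
  if (!any(inside)) return(NA_real_)
  mean(r$values[inside], na.rm = TRUE)
}

#' Write a raster as an ESRI ASCII grid
#'
#' @param r A `grid_raster`.
#' @param path Output path (conventionally `.asc`).
#' @param nodata Value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(v)), paste("nrows", nrow(v)),
    paste("xllcorner", r$xmin), paste("yllcorner", r$ymin),
    paste("cellsize", r$cellsize), paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @param name Band name for the result.
#' @return A `grid_raster`.
#' @export
read_asc <- function(path, name = "band") {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr), "\\s+")
  key <- tolower(vapply(kv, `[`, "", 1))
  val <- as.numeric(vapply(kv, `[`, "", 2))
  names(val) <- key
  v <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(v) <- NULL
  v[v == val[["nodata_value"]]] <- NA
  grid_raster(v, val[["xllcorner"]], val[["yllcorner"]], val[["cellsize"]],
              name = name)
}

#' Constant raster helper
#'
#' @param value Fill value.
#' @param half_extent Half-width of the square raster (km).
#' @param cellsize Cell size (km).
#' @param name Band name.
#' @return A `grid_raster` centred on the origin.
#' @export
constant_raster <- function(value, half_extent = 32.5, cellsize = 1,
                            name = "const") {
  n <- ceiling(2 * half_extent / cellsize)
  grid_raster(matrix(value, n, n), -half_extent, -half_extent, cellsize, name)
}
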