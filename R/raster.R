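#' Gridded rasters on a window
#'
#' Light container for gridded values (residential density in residents/km^2,
#' or any cell-wise quantity). Values are stored as a matrix with `ny` rows and
#' `nx` columns; row `iy` corresponds to the cell row with centre
#' `y0 + (iy - 0.5) * cell_size_m`, i.e. rows run south to north.
#'
#' @param values numeric matrix `[ny, nx]` of cell values.
#' @param origin lower-left corner of the grid, numeric length-2 (metres).
#' @param cell_size_m cell edge length in metres.
#' @param units free-text unit label carried along for printing.
#' @return an object of class `kh_raster`.
#' @export
kh_raster <- function(values, origin = c(0, 0), cell_size_m, units = "") {
  stopifnot(is.matrix(values))
  assert_scalar_pos(cell_size_m, "cell_size_m")
  structure(
    list(
      values = values,
      x0 = origin[[1]], y0 = origin[[2]],
      nx = ncol(values), ny = nrow(values),
      cell_size_m = cell_size_m,
      units = units
    ),
    class = "kh_raster"
  )
}

raster_xcenters <- function(r) r$x0 + (seq_len(r$nx) - 0.5) * r$cell_size_m
raster_ycenters <- function(r) r$y0 + (seq_len(r$ny) - 0.5) * r$cell_size_m

#' Look up raster values at point locations
#'
#' Nearest-cell lookup; coordinates outside the grid are clamped to the edge
#' cells.
#'
#' @param raster a `kh_raster`.
#' @param x,y coordinates in metres.
#' @return numeric vector of cell values.
#' @export
raster_at <- function(raster, x, y) {
  stopifnot(inherits(raster, "kh_raster"))
  ix <- pmin(raster$nx, pmax(1L, floor((x - raster$x0) / raster$cell_size_m) + 1L))
  iy <- pmin(raster$ny, pmax(1L, floor((y - raster$y0) / raster$cell_size_m) + 1L))
  raster$values[cbind(iy, ix)]
}

raster_cell_km2 <- function(raster) (raster$cell_size_m / 1000)^2

#' Total implied residents of a density raster
#'
#' Integrates a residents/km^2 raster over its cells.
#'
#' @param raster a `kh_raster` holding residential density in residents/km^2.
#' @return total residents (numeric scalar).
#' @export
raster_total_residents <- function(raster) {
  sum(raster$values) * raster_cell_km2(raster)
}

#' @export
print.kh_raster <- function(x, ...) {
  cat(sprintf(
    "<kh_raster> %d x %d cells of %.0f m %s; range [%.3g, %.3g]\n",
    x$nx, x$ny, x$cell_size_m, x$units, min(x$values), max(x$values)
  ))
  invisible(x)
}

#' @export
tidy.kh_raster <- function(x, ...) {
  xs <- rep(raster_xcenters(x), each = x$ny)
  ys <- rep(raster_ycenters(x), times = x$nx)
  vals <- as.vector(x$values)
  tibble(x = xs, y = ys, value = vals)
}

#' @export
autoplot.kh_raster <- function(object, ...) {
  df <- tidy.kh_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = object$units) +
    ggplot2::labs(x = "x [m]", y = "y [m]")
}
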