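#' Observation windows
#'
#' A window is the planar region `W` that contains the study area: all point
#' patterns, rasters and street networks live inside one window. Coordinates
#' are metric (metres) and CRS-agnostic; areas are reported in km^2.
#'
#' @param width_m,height_m rectangle extents in metres.
#' @param origin numeric length-2, lower-left corner.
#' @return an object of class `kh_window`.
#' @examples
#' w <- window_rect(2000, 1500)
#' window_area_km2(w)
#' @export
window_rect <- function(width_m, height_m, origin = c(0, 0)) {
  assert_scalar_pos(width_m, "width_m")
  assert_scalar_pos(height_m, "height_m")
  x0 <- origin[[1]]
  y0 <- origin[[2]]
  vx <- c(x0, x0 + width_m, x0 + width_m, x0)
  vy <- c(y0, y0, y0 + height_m, y0 + height_m)
  structure(
    list(
      x = vx, y = vy,
      xmin = x0, xmax = x0 + width_m, ymin = y0, ymax = y0 + height_m,
      is_rect = TRUE,
      area_m2 = width_m * height_m
    ),
    class = "kh_window"
  )
}

#' @param x,y polygon vertex coordinates (metres), in order, not closed.
#' @rdname window_rect
#' @export
window_polygon <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    abort("window vertices must be finite")
  }
  a2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) # shoelace, signed * 2
  if (abs(a2) < 1e-9) abort("window polygon has zero area")
  if (a2 < 0) { # enforce counter-clockwise orientation
    x <- rev(x)
    y <- rev(y)
    a2 <- -a2
  }
  structure(
    list(
      x = x, y = y,
      xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y),
      is_rect = FALSE,
      area_m2 = a2 / 2
    ),
    class = "kh_window"
  )
}

#' @param window a `kh_window`.
#' @rdname window_rect
#' @export
window_area_km2 <- function(window) {
  stopifnot(inherits(window, "kh_window"))
  window$area_m2 / 1e6
}

window_diameter <- function(window) {
  sqrt((window$xmax - window$xmin)^2 + (window$ymax - window$ymin)^2)
}

#' Test whether points fall inside a window
#'
#' Boundary points count as inside. Rectangles use direct comparison; general
#' polygons use ray casting.
#'
#' @param window a `kh_window`.
#' @param x,y point coordinates (metres).
#' @return logical vector.
#' @export
in_window <- function(window, x, y) {
  stopifnot(inherits(window, "kh_window"), length(x) == length(y))
  if (window$is_rect) {
    return(x >= window$xmin & x <= window$xmax &
      y >= window$ymin & y <= window$ymax)
  }
  vx <- window$x
  vy <- window$y
  nv <- length(vx)
  inside <- logical(length(x))
  jj <- c(nv, seq_len(nv - 1L))
  for (k in seq_len(nv)) {
    x1 <- vx[jj[k]]; y1 <- vy[jj[k]]
    x2 <- vx[k]; y2 <- vy[k]
    crosses <- ((y2 > y) != (y1 > y)) &
      (x < (x1 - x2) * (y - y2) / (y1 - y2) + x2)
    inside <- xor(inside, crosses)
    on_edge <- dist_point_segment(x, y, x1, y1, x2, y2) < 1e-9
    inside <- inside | on_edge
  }
  inside
}

#' @export
print.kh_window <- function(x, ...) {
  cat(sprintf(
    "<kh_window> %s, [%.0f, %.0f] x [%.0f, %.0f] m, area %.4f km^2\n",
    if (x$is_rect) "rectangle" else sprintf("polygon (%d vertices)", length(x$x)),
    x$xmin, x$xmax, x$ymin, x$ymax, x$area_m2 / 1e6
  ))
  invisible(x)
}
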