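#' Planar point patterns
#'
#' A point pattern holds the locations of one kind of urban point
#' characteristic (street intersections, public transit stations, or public
#' open spaces) inside an observation window. Exact duplicate locations are
#' allowed (two playgrounds can share a snapped coordinate); points outside
#' the window and non-finite coordinates are rejected.
#'
#' @param x,y point coordinates in metres.
#' @param window a [window_rect()] / [window_polygon()] object.
#' @param kind one of `"intersections"`, `"transit"`, `"open_space"`, or any
#'   free-text layer label.
#' @return an object of class `kh_pattern`.
#' @examples
#' w <- window_rect(1000, 1000)
#' p <- point_pattern(runif(20, 0, 1000), runif(20, 0, 1000), w, "open_space")
#' npoints(p)
#' @export
point_pattern <- function(x, y, window, kind = "points") {
  stopifnot(inherits(window, "kh_window"), length(x) == length(y))
  if (length(x) > 0 && (any(!is.finite(x)) || any(!is.finite(y)))) {
    abort("point coordinates must be finite")
  }
  if (length(x) > 0 && !all(in_window(window, x, y))) {
    abort("all points must lie inside the window")
  }
  structure(
    list(x = as.numeric(x), y = as.numeric(y), window = window, kind = kind),
    class = "kh_pattern"
  )
}

#' @param pattern a `kh_pattern`.
#' @rdname point_pattern
#' @export
npoints <- function(pattern) {
  stopifnot(inherits(pattern, "kh_pattern"))
  length(pattern$x)
}

#' @export
print.kh_pattern <- function(x, ...) {
  cat(sprintf("<kh_pattern> kind '%s', %d points in %.4f km^2 window\n",
    x$kind, length(x$x), window_area_km2(x$window)))
  invisible(x)
}

#' @export
tidy.kh_pattern <- function(x, ...) {
  tibble(x = x$x, y = x$y, kind = x$kind)
}

#' Simple intensity of a point pattern in a region
#'
#' The homogeneous ("simple") intensity of a region `A` is the number of
#' pattern points falling in `A` (boundary inclusive) divided by its area
#' `nu(A)`, reported in points per km^2. The region may be the full window,
#' any polygonal sub-window, or a network [service_area()].
#'
#' @param pattern a [point_pattern()].
#' @param region a `kh_window` polygon or a `kh_service_area`.
#' @return intensity in points/km^2 (scalar).
#' @examples
#' w <- window_rect(1000, 500) # 0.5 km^2
#' p <- point_pattern(c(100, 200, 300), c(100, 200, 300), w)
#' simple_intensity(p, w) # 6 points/km^2
#' @export
simple_intensity <- function(pattern, region) {
  stopifnot(inherits(pattern, "kh_pattern"))
  if (inherits(region, "kh_service_area")) {
    area_km2 <- region$area_km2
    if (area_km2 <= 0) abort("region has zero area")
    inside <- sa_contains(region, pattern$x, pattern$y)
  } else if (inherits(region, "kh_window")) {
    area_km2 <- window_area_km2(region)
    if (area_km2 <= 0) abort("region has zero area")
    inside <- in_window(region, pattern$x, pattern$y)
  } else {
    abort("`region` must be a kh_window or kh_service_area")
  }
  sum(inside) / area_km2
}
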