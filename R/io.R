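# ---- plain-text spatial and tabular IO ----------------------------------
#
# All geometry is CRS-agnostic planar metres: GeoJSON files carry raw metric
# coordinates (no CRS transform), rasters use the ESRI ASCII grid dialect.

#' Write and read point layers as GeoJSON
#'
#' @param pattern a [point_pattern()].
#' @param path output file.
#' @return `write_geojson_points()` returns `path` invisibly;
#'   `read_geojson_points()` returns a [point_pattern()].
#' @export
write_geojson_points <- function(pattern, path) {
  stopifnot(inherits(pattern, "kh_pattern"))
  features <- lapply(seq_along(pattern$x), function(i) {
    list(
      type = "Feature",
      properties = list(kind = pattern$kind, id = i),
      geometry = list(type = "Point",
        coordinates = c(pattern$x[i], pattern$y[i]))
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param window window for the read pattern.
#' @param kind layer kind label (defaults to the stored property).
#' @rdname write_geojson_points
#' @export
read_geojson_points <- function(path, window, kind = NULL) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    abort("not a GeoJSON FeatureCollection")
  }
  coords <- vapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "Point")) {
      abort("expected Point geometries")
    }
    as.numeric(unlist(f$geometry$coordinates))[1:2]
  }, numeric(2))
  k <- kind %||% (fc$features[[1]]$properties$kind %||% "points")
  if (length(fc$features) == 0L) {
    return(point_pattern(numeric(0), numeric(0), window, kind = k %||% "points"))
  }
  point_pattern(coords[1, ], coords[2, ], window, kind = k)
}

#' Write and read street networks as GeoJSON LineStrings
#'
#' Each edge becomes a two-point LineString with `from`/`to` node ids in the
#' properties; node coordinates are recovered from the line endpoints.
#'
#' @param network a [street_network()].
#' @param path file path.
#' @return `write_geojson_network()` returns `path` invisibly;
#'   `read_geojson_network()` returns a [street_network()].
#' @export
write_geojson_network <- function(network, path) {
  stopifnot(inherits(network, "kh_network"))
  e <- network$edges
  features <- lapply(seq_len(nrow(e)), function(i) {
    list(
      type = "Feature",
      properties = list(edge_id = e$edge_id[i], from = e$from[i], to = e$to[i]),
      geometry = list(type = "LineString",
        coordinates = list(c(e$x1[i], e$y1[i]), c(e$x2[i], e$y2[i])))
    )
  })
  fc <- list(
    type = "FeatureCollection",
    properties = list(
      window = list(width_m = network$window$xmax - network$window$xmin,
        height_m = network$window$ymax - network$window$ymin,
        origin = c(network$window$xmin, network$window$ymin))
    ),
    features = features
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geojson_network
#' @export
read_geojson_network <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    abort("not a GeoJSON FeatureCollection")
  }
  w <- fc$properties$window
  window <- window_rect(w$width_m, w$height_m,
    origin = as.numeric(unlist(w$origin)))
  rows <- lapply(fc$features, function(f) {
    if (!identical(f$geometry$type, "LineString")) {
      abort("expected LineString geometries")
    }
    cc <- f$geometry$coordinates
    tibble(
      from = f$properties$from, to = f$properties$to,
      x1 = as.numeric(cc[[1]][[1]]), y1 = as.numeric(cc[[1]][[2]]),
      x2 = as.numeric(cc[[2]][[1]]), y2 = as.numeric(cc[[2]][[2]])
    )
  })
  ed <- bind_rows(rows)
  node_key <- function(x, y) paste(round(x, 3), round(y, 3))
  keys <- unique(c(node_key(ed$x1, ed$y1), node_key(ed$x2, ed$y2)))
  all_x <- c(ed$x1, ed$x2)[match(keys, c(node_key(ed$x1, ed$y1), node_key(ed$x2, ed$y2)))]
  all_y <- c(ed$y1, ed$y2)[match(keys, c(node_key(ed$x1, ed$y1), node_key(ed$x2, ed$y2)))]
  nodes <- tibble(id = seq_along(keys), x = all_x, y = all_y)
  edges <- tibble(
    from = nodes$id[match(node_key(ed$x1, ed$y1), keys)],
    to = nodes$id[match(node_key(ed$x2, ed$y2), keys)]
  )
  street_network(nodes, edges, window)
}

#' Write a service area as GeoJSON
#'
#' Exports the reached edge fragments as LineStrings with the origin,
#' network distance, buffer width, reached length and area in the
#' collection properties (the buffered polygon is reconstructible from
#' fragments + buffer).
#'
#' @param area a [service_area()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_geojson_service_area <- function(area, path) {
  stopifnot(inherits(area, "kh_service_area"))
  fr <- area$fragments
  features <- lapply(seq_len(nrow(fr)), function(i) {
    list(
      type = "Feature",
      properties = list(edge_id = fr$edge_id[i], t0 = fr$t0[i], t1 = fr$t1[i]),
      geometry = list(type = "LineString",
        coordinates = list(c(fr$x1[i], fr$y1[i]), c(fr$x2[i], fr$y2[i])))
    )
  })
  fc <- list(
    type = "FeatureCollection",
    properties = list(
      child_id = area$child_id,
      origin = c(area$origin$x, area$origin$y),
      distance_m = area$distance_m,
      buffer_m = area$buffer_m,
      reached_length_m = area$reached_length_m,
      area_km2 = area$area_km2
    ),
    features = features
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write and read rasters as ESRI ASCII grids
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value` header
#' followed by rows north to south. Intensity surfaces carry a JSON sidecar
#' (`<path>.json`) recording the bandwidth provenance.
#'
#' @param raster a `kh_raster` or `kh_surface`.
#' @param path file path.
#' @param digits significant digits written.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a `kh_raster`.
#' @export
write_ascii_grid <- function(raster, path, digits = 8) {
  stopifnot(inherits(raster, "kh_raster"))
  hdr <- c(
    sprintf("ncols %d", raster$nx),
    sprintf("nrows %d", raster$ny),
    sprintf("xllcorner %.6f", raster$x0),
    sprintf("yllcorner %.6f", raster$y0),
    sprintf("cellsize %.6f", raster$cell_size_m),
    "NODATA_value -9999"
  )
  vals <- raster$values
  vals[is.na(vals)] <- -9999
  body <- apply(vals[rev(seq_len(raster$ny)), , drop = FALSE], 1, function(r) {
    paste(signif(r, digits), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  if (inherits(raster, "kh_surface")) {
    bw <- raster$bandwidth
    jsonlite::write_json(list(
      kind = raster$kind, edge_corrected = raster$edge_corrected,
      n_points = raster$n_points,
      bandwidth = list(form = bw$form, sigma_m = bw$sigma_m,
        Sigma = bw$Sigma, provenance = bw$provenance)
    ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  get <- function(key) {
    i <- which(vapply(hdr, function(h) h[1] == key, logical(1)))
    if (!length(i)) abort(sprintf("missing '%s' in ASCII grid header", key))
    as.numeric(hdr[[i]][2])
  }
  nx <- get("ncols")
  ny <- get("nrows")
  nodata <- get("nodata_value")
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (!all(dim(vals) == c(ny, nx))) abort("ASCII grid body does not match header")
  vals[vals == nodata] <- NA_real_
  kh_raster(vals[rev(seq_len(ny)), , drop = FALSE],
    origin = c(get("xllcorner"), get("yllcorner")),
    cell_size_m = get("cellsize"))
}

#' Write a cohort or exposure table as CSV
#'
#' Thin wrappers around readr with stable column ordering, so identical
#' inputs give byte-identical files.
#'
#' @param x tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
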