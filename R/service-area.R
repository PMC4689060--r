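# ---- network reach geometry ---------------------------------------------
#
# A service area is the set of planar points within `buffer_m` of the network
# fragments reachable within a network distance D from an origin. For a query
# point c and an edge (u, v) of length L with origin-to-node distances du, dv,
# the set of on-edge positions t whose buffered disc covers c is a chord
# interval [ta, tb]; the smallest network distance among those positions is
# attained at an interval end. Minimising over edges yields the "network
# reach" of c: c lies in the service area of distance D iff reach(c) <= D.
# This gives exact membership for every distance from one pass over the edges.

# interval of arc positions on a segment within `buffer` of (px, py);
# returns ta, tb (NA when the disc misses the line) for vectors of points
chord_interval <- function(px, py, x1, y1, x2, y2, L, buffer) {
  ux <- (x2 - x1) / L
  uy <- (y2 - y1) / L
  rx <- px - x1
  ry <- py - y1
  t_raw <- rx * ux + ry * uy
  dperp <- abs(-rx * uy + ry * ux)
  s <- suppressWarnings(sqrt(buffer^2 - dperp^2))
  ta <- pmax(0, t_raw - s)
  tb <- pmin(L, t_raw + s)
  bad <- !is.finite(s) | (ta > tb)
  ta[bad] <- NA_real_
  tb[bad] <- NA_real_
  list(ta = ta, tb = tb)
}

# network reach values at arbitrary query points: vectorised point-by-edge
# cross product, chunked over edges to bound memory
reach_points <- function(px, py, edges, du, dv, origin, buffer,
                         chunk = 4e6) {
  np <- length(px)
  out <- rep(Inf, np)
  if (np == 0L || nrow(edges) == 0L) return(out)
  live <- which(is.finite(du) | is.finite(dv) |
    (!is.null(origin) & edges$edge_id == origin$edge_id))
  if (length(live) == 0L) return(out)
  step <- max(1L, floor(chunk / np))
  for (start in seq(1L, length(live), by = step)) {
    sel <- live[start:min(length(live), start + step - 1L)]
    ne <- length(sel)
    eidx <- rep(sel, each = np)
    L <- edges$length_m[eidx]
    ux <- (edges$x2[eidx] - edges$x1[eidx]) / L
    uy <- (edges$y2[eidx] - edges$y1[eidx]) / L
    rx <- rep.int(px, ne) - edges$x1[eidx]
    ry <- rep.int(py, ne) - edges$y1[eidx]
    t_raw <- rx * ux + ry * uy
    dperp <- abs(-rx * uy + ry * ux)
    s <- suppressWarnings(sqrt(buffer^2 - dperp^2))
    ta <- pmax(0, t_raw - s)
    tb <- pmin(L, t_raw + s)
    val <- pmin(du[eidx] + ta, dv[eidx] + (L - tb))
    if (!is.null(origin)) {
      on_host <- edges$edge_id[eidx] == origin$edge_id
      if (any(on_host)) {
        a <- origin$t
        v <- ifelse(ta[on_host] <= a & a <= tb[on_host], 0,
          pmin(abs(ta[on_host] - a), abs(tb[on_host] - a)))
        val[on_host] <- pmin(val[on_host], v)
      }
    }
    val[!is.finite(s) | ta > tb] <- Inf
    val[is.na(val)] <- Inf
    for (j in seq_len(ne)) {
      out <- pmin(out, val[((j - 1L) * np + 1L):(j * np)])
    }
  }
  out
}

# network reach on a structured grid (gx, gy cell centres); returns a
# [length(gy), length(gx)] matrix. All edges are processed in one
# vectorised pass: candidate cells are enumerated per edge bounding box,
# and the per-cell minimum is realised by assigning values in decreasing
# order (the smallest write wins last).
reach_grid <- function(gx, gy, edges, du, dv, origin, buffer) {
  ny <- length(gy)
  nx <- length(gx)
  R <- matrix(Inf, nrow = ny, ncol = nx)
  if (nx == 0L || ny == 0L || nrow(edges) == 0L) return(R)
  h_x <- if (nx > 1) gx[2] - gx[1] else 1
  h_y <- if (ny > 1) gy[2] - gy[1] else 1
  live <- which(is.finite(du) | is.finite(dv) |
    (!is.null(origin) & edges$edge_id == origin$edge_id))
  if (length(live) == 0L) return(R)
  e <- edges[live, , drop = FALSE]
  duL <- du[live]
  dvL <- dv[live]
  ix0 <- pmax(1L, floor((pmin(e$x1, e$x2) - buffer - gx[1]) / h_x) + 1L)
  ix1 <- pmin(nx, ceiling((pmax(e$x1, e$x2) + buffer - gx[1]) / h_x) + 1L)
  iy0 <- pmax(1L, floor((pmin(e$y1, e$y2) - buffer - gy[1]) / h_y) + 1L)
  iy1 <- pmin(ny, ceiling((pmax(e$y1, e$y2) + buffer - gy[1]) / h_y) + 1L)
  nxi <- ix1 - ix0 + 1L
  nyi <- iy1 - iy0 + 1L
  keep <- nxi > 0L & nyi > 0L
  if (!any(keep)) return(R)
  e <- e[keep, , drop = FALSE]
  duL <- duL[keep]; dvL <- dvL[keep]
  ix0 <- ix0[keep]; iy0 <- iy0[keep]
  nxi <- nxi[keep]; nyi <- nyi[keep]
  cnt <- nxi * nyi
  eidx <- rep.int(seq_along(cnt), cnt)
  k <- sequence(cnt) - 1L
  ix <- ix0[eidx] + k %/% nyi[eidx]
  iy <- iy0[eidx] + k %% nyi[eidx]
  px <- gx[ix]
  py <- gy[iy]
  L <- e$length_m[eidx]
  ux <- (e$x2[eidx] - e$x1[eidx]) / L
  uy <- (e$y2[eidx] - e$y1[eidx]) / L
  rx <- px - e$x1[eidx]
  ry <- py - e$y1[eidx]
  t_raw <- rx * ux + ry * uy
  dperp <- abs(-rx * uy + ry * ux)
  s <- suppressWarnings(sqrt(buffer^2 - dperp^2))
  ta <- pmax(0, t_raw - s)
  tb <- pmin(L, t_raw + s)
  val <- pmin(duL[eidx] + ta, dvL[eidx] + (L - tb))
  if (!is.null(origin)) {
    on_host <- e$edge_id[eidx] == origin$edge_id
    if (any(on_host)) {
      a <- origin$t
      v <- ifelse(ta[on_host] <= a & a <= tb[on_host], 0,
        pmin(abs(ta[on_host] - a), abs(tb[on_host] - a)))
      val[on_host] <- pmin(val[on_host], v)
    }
  }
  ok <- is.finite(s) & (ta <= tb) & is.finite(val)
  if (!any(ok)) return(R)
  cell <- (ix[ok] - 1L) * ny + iy[ok]
  v <- val[ok]
  ord <- order(v, decreasing = TRUE)
  R[cell[ord]] <- v[ord]
  R
}

# reachable edge fragments at network distance D (intervals of arc position,
# merged per edge), as a tibble with fragment endpoint coordinates
reach_fragments <- function(edges, du, dv, origin, D) {
  ne <- nrow(edges)
  cap <- 3L * max(ne, 1L)
  o_eid <- numeric(cap)
  o_t0 <- numeric(cap)
  o_t1 <- numeric(cap)
  o_i <- integer(cap)
  n_out <- 0L
  for (i in seq_len(ne)) {
    L <- edges$length_m[i]
    a0 <- numeric(3)
    a1 <- numeric(3)
    k <- 0L
    if (is.finite(du[i]) && D >= du[i]) {
      k <- k + 1L; a0[k] <- 0; a1[k] <- min(L, D - du[i])
    }
    if (is.finite(dv[i]) && D >= dv[i]) {
      k <- k + 1L; a0[k] <- max(0, L - (D - dv[i])); a1[k] <- L
    }
    if (!is.null(origin) && edges$edge_id[i] == origin$edge_id) {
      k <- k + 1L; a0[k] <- max(0, origin$t - D); a1[k] <- min(L, origin$t + D)
    }
    if (k == 0L) next
    ord <- order(a0[1:k])
    a0 <- a0[ord]; a1 <- a1[ord]
    m0 <- a0[1]; m1 <- a1[1]
    for (j in seq_len(k)[-1]) {
      if (a0[j] <= m1 + 1e-9) {
        m1 <- max(m1, a1[j])
      } else {
        if (m1 - m0 > 1e-9) {
          n_out <- n_out + 1L
          o_eid[n_out] <- edges$edge_id[i]; o_t0[n_out] <- m0
          o_t1[n_out] <- m1; o_i[n_out] <- i
        }
        m0 <- a0[j]; m1 <- a1[j]
      }
    }
    if (m1 - m0 > 1e-9) {
      n_out <- n_out + 1L
      o_eid[n_out] <- edges$edge_id[i]; o_t0[n_out] <- m0
      o_t1[n_out] <- m1; o_i[n_out] <- i
    }
  }
  sel <- seq_len(n_out)
  i <- o_i[sel]
  L <- edges$length_m[i]
  ux <- (edges$x2[i] - edges$x1[i]) / L
  uy <- (edges$y2[i] - edges$y1[i]) / L
  tibble(
    edge_id = o_eid[sel], t0 = o_t0[sel], t1 = o_t1[sel],
    x1 = edges$x1[i] + o_t0[sel] * ux, y1 = edges$y1[i] + o_t0[sel] * uy,
    x2 = edges$x1[i] + o_t1[sel] * ux, y2 = edges$y1[i] + o_t1[sel] * uy
  )
}

# ---- service areas -------------------------------------------------------

#' Ego-centered network-distance neighborhood (service area)
#'
#' Builds the neighborhood reachable within `distance_m` along the street
#' network from an origin: single-source shortest paths retain every edge
#' fragment whose network distance is at most `distance_m` (partial edges are
#' cut at the exact reach point), and the neighborhood polygon is the union
#' of those fragments buffered by `buffer_m`, clipped to the window. The area
#' `nu(A)` is computed on a fine grid (resolution `buffer_m / 5` by default)
#' with sub-cell refinement of boundary cells.
#'
#' @param network a [street_network()].
#' @param origin a [snap_to_network()] result, or a length-2 numeric `c(x, y)`
#'   which is snapped first.
#' @param distance_m network distance in metres (the study distances are 500,
#'   750, 1000, 1250, 1500, 2000).
#' @param buffer_m buffer width around reached edges (metres, default 25).
#' @param area_resolution_m grid resolution for the area computation.
#' @param child_id optional identifier carried through.
#' @return an object of class `kh_service_area` with the reached fragments,
#'   reached network length, polygon area in km^2, and the reach geometry
#'   needed for point-membership queries.
#' @export
service_area <- function(network, origin, distance_m, buffer_m = 25,
                         area_resolution_m = NULL, child_id = NA_character_) {
  stopifnot(inherits(network, "kh_network"))
  assert_scalar_pos(distance_m, "distance_m")
  assert_scalar_pos(buffer_m, "buffer_m")
  if (is.numeric(origin) && length(origin) == 2L) {
    origin <- snap_to_network(origin[1], origin[2], network)
  }
  du_dv <- origin_node_distances(network, origin)
  sa_build(network, origin, du_dv$du, du_dv$dv, distance_m, buffer_m,
    area_resolution_m, child_id)
}

# restrict to edges that can contribute at distance D (origin host edge is
# always kept); exact because an edge with both node distances > D carries
# no reachable fragment
filter_edges <- function(edges, du, dv, origin, D) {
  keep <- which(pmin(du, dv) <= D | edges$edge_id == origin$edge_id)
  list(edges = edges[keep, , drop = FALSE], du = du[keep], dv = dv[keep])
}

# per-edge origin distances (du = to `from` node, dv = to `to` node)
origin_node_distances <- function(network, origin) {
  nd <- node_distances_from(network, origin)
  idx_from <- match(network$edges$from, network$nodes$id)
  idx_to <- match(network$edges$to, network$nodes$id)
  list(du = nd[idx_from], dv = nd[idx_to])
}

sa_build <- function(network, origin, du, dv, distance_m, buffer_m,
                     area_resolution_m = NULL, child_id = NA_character_) {
  fe <- filter_edges(network$edges, du, dv, origin, distance_m)
  edges <- fe$edges
  du <- fe$du
  dv <- fe$dv
  window <- network$window
  frags <- reach_fragments(edges, du, dv, origin, distance_m)
  reached_length <- sum(frags$t1 - frags$t0)
  if (reached_length < distance_m / 10) {
    warn(sprintf(
      "isolated origin: reachable network length %.0f m is below distance/10",
      reached_length))
  }
  res <- area_resolution_m %||% (buffer_m / 5)
  geom <- list(edges = edges, du = du, dv = dv, origin = origin,
    buffer = buffer_m)
  area_km2 <- sa_area(geom, frags, distance_m, res, window)
  structure(
    list(
      child_id = child_id, origin = origin, distance_m = distance_m,
      buffer_m = buffer_m, fragments = frags,
      reached_length_m = reached_length, area_km2 = area_km2,
      geom = geom, window = window
    ),
    class = "kh_service_area"
  )
}

# area of the buffered fragment union (km^2), fine-grid count with 4x4
# sub-sampling of mask-boundary cells, clipped to the window
sa_area <- function(geom, frags, D, res, window) {
  if (nrow(frags) == 0L) return(0)
  b <- geom$buffer
  xlo <- max(window$xmin, min(frags$x1, frags$x2) - b)
  xhi <- min(window$xmax, max(frags$x1, frags$x2) + b)
  ylo <- max(window$ymin, min(frags$y1, frags$y2) - b)
  yhi <- min(window$ymax, max(frags$y1, frags$y2) + b)
  gx <- seq(xlo + res / 2, xhi, by = res)
  gy <- seq(ylo + res / 2, yhi, by = res)
  R <- reach_grid(gx, gy, geom$edges, geom$du, geom$dv, geom$origin, b)
  M <- R <= D
  if (!window$is_rect) {
    cx <- rep(gx, each = length(gy))
    cy <- rep(gy, times = length(gx))
    M <- M & matrix(in_window(window, cx, cy), nrow = length(gy))
  }
  # boundary cells: any 4-neighbour differs (padded with FALSE)
  ny <- nrow(M); nx <- ncol(M)
  pad <- function(m, di, dj) {
    out <- matrix(FALSE, ny, nx)
    ri <- max(1, 1 + di):min(ny, ny + di)
    rj <- max(1, 1 + dj):min(nx, nx + dj)
    out[ri, rj] <- m[ri - di, rj - dj]
    out
  }
  nb_diff <- (M != pad(M, 1, 0)) | (M != pad(M, -1, 0)) |
    (M != pad(M, 0, 1)) | (M != pad(M, 0, -1))
  # cells on the grid rim whose centre is covered also get refined
  rim <- matrix(FALSE, ny, nx)
  rim[c(1, ny), ] <- TRUE
  rim[, c(1, nx)] <- TRUE
  boundary <- nb_diff | (rim & M)
  full <- M & !boundary
  area_m2 <- sum(full) * res^2
  bidx <- which(boundary, arr.ind = TRUE)
  # sub-cell refinement pays off only while the boundary set is small (its
  # discretisation error self-averages along long, irregular outlines);
  # past the cap, boundary cells are counted by their centres
  if (nrow(bidx) > 5000) {
    return((area_m2 + sum(M & boundary) * res^2) / 1e6)
  }
  if (nrow(bidx) > 0) {
    k <- 4L
    off <- (seq_len(k) - 0.5) / k - 0.5
    sx <- rep(gx[bidx[, 2]], each = k * k) +
      rep(rep(off * res, times = k), times = nrow(bidx))
    sy <- rep(gy[bidx[, 1]], each = k * k) +
      rep(rep(off * res, each = k), times = nrow(bidx))
    rsub <- reach_points(sx, sy, geom$edges, geom$du, geom$dv, geom$origin, b)
    inside <- rsub <= D
    if (!window$is_rect) {
      inside <- inside & in_window(window, sx, sy)
    } else {
      inside <- inside & sx >= window$xmin & sx <= window$xmax &
        sy >= window$ymin & sy <= window$ymax
    }
    frac <- colMeans(matrix(inside, nrow = k * k))
    area_m2 <- area_m2 + sum(frac) * res^2
  }
  area_m2 / 1e6
}

# point membership in the service-area polygon
sa_contains <- function(area, px, py) {
  stopifnot(inherits(area, "kh_service_area"))
  if (length(px) == 0L) return(logical(0))
  r <- reach_points(px, py, area$geom$edges, area$geom$du, area$geom$dv,
    area$geom$origin, area$geom$buffer)
  inside <- r <= area$distance_m
  inside & in_window(area$window, px, py)
}

#' @export
print.kh_service_area <- function(x, ...) {
  cat(sprintf(
    "<kh_service_area> distance %.0f m, buffer %.0f m: %.1f km of network reached, area %.4f km^2\n",
    x$distance_m, x$buffer_m, x$reached_length_m / 1000, x$area_km2))
  invisible(x)
}

#' @export
tidy.kh_service_area <- function(x, ...) {
  x$fragments
}

#' Mean residential density inside a service area
#'
#' Area-weighted mean of a residents/km^2 raster over the service-area
#' polygon, evaluated on the fine area grid (cells clipped at the boundary).
#' Used as `R_A` for [adaptive_scale()].
#'
#' @param area a [service_area()].
#' @param raster a `kh_raster` of residents/km^2.
#' @param resolution_m sampling resolution (defaults to `buffer_m / 5`).
#' @return mean density, residents/km^2.
#' @export
residential_density_in <- function(area, raster, resolution_m = NULL) {
  stopifnot(inherits(area, "kh_service_area"), inherits(raster, "kh_raster"))
  res <- resolution_m %||% (area$buffer_m / 5)
  frags <- area$fragments
  if (nrow(frags) == 0L) {
    return(raster_at(raster, area$origin$x, area$origin$y))
  }
  b <- area$buffer_m
  w <- area$window
  xlo <- max(w$xmin, min(frags$x1, frags$x2) - b)
  xhi <- min(w$xmax, max(frags$x1, frags$x2) + b)
  ylo <- max(w$ymin, min(frags$y1, frags$y2) - b)
  yhi <- min(w$ymax, max(frags$y1, frags$y2) + b)
  gx <- seq(xlo + res / 2, xhi, by = res)
  gy <- seq(ylo + res / 2, yhi, by = res)
  R <- reach_grid(gx, gy, area$geom$edges, area$geom$du, area$geom$dv,
    area$geom$origin, b)
  M <- R <= area$distance_m
  if (!any(M)) {
    return(raster_at(raster, area$origin$x, area$origin$y))
  }
  cx <- rep(gx, each = length(gy))[as.vector(M)]
  cy <- rep(gy, times = length(gx))[as.vector(M)]
  mean(raster_at(raster, cx, cy))
}

#' Mean kernel intensity inside a service area
#'
#' Mean of the intensity surface over the grid cells whose centres fall in
#' the service-area polygon. When no cell centre falls inside (a very small
#' area), the surface is bilinearly evaluated at the origin instead and the
#' result is flagged with attribute `fallback = TRUE`.
#'
#' @param area a [service_area()].
#' @param surface a [kernel_intensity_surface()].
#' @return mean intensity, points/km^2.
#' @export
mean_intensity_in <- function(area, surface) {
  stopifnot(inherits(area, "kh_service_area"), inherits(surface, "kh_surface"))
  gx <- surface$x0 + (seq_len(surface$nx) - 0.5) * surface$cell_size_m
  gy <- surface$y0 + (seq_len(surface$ny) - 0.5) * surface$cell_size_m
  R <- reach_grid(gx, gy, area$geom$edges, area$geom$du, area$geom$dv,
    area$geom$origin, area$buffer_m)
  M <- (R <= area$distance_m) & !is.na(surface$values)
  if (!any(M)) {
    out <- surface_at(surface, area$origin$x, area$origin$y)
    attr(out, "fallback") <- TRUE
    return(out)
  }
  mean(surface$values[M])
}

#' Privacy-preserving residence blurring
#'
#' Displaces a residence by bivariate Gaussian noise whose standard deviation
#' is inversely proportional to the residential density at the home:
#' `sd = c / density`, so that densely populated areas receive small shifts
#' (about 50-100 m at high density with the default scale) and sparse areas
#' larger ones. Draws falling outside the window are redrawn (up to 100
#' times). Deterministic under the spec's seed.
#'
#' @param x,y home coordinates (metres).
#' @param density_raster residents/km^2 `kh_raster`.
#' @param spec a [blur_spec()].
#' @param window a `kh_window` (defaults to the raster extent).
#' @return list with blurred `x`, `y`, the `sd_m` used and `displacement_m`.
#' @export
blur_residence <- function(x, y, density_raster, spec, window = NULL) {
  stopifnot(inherits(density_raster, "kh_raster"))
  if (is.null(window)) {
    window <- window_rect(
      density_raster$nx * density_raster$cell_size_m,
      density_raster$ny * density_raster$cell_size_m,
      origin = c(density_raster$x0, density_raster$y0))
  }
  dens <- max(raster_at(density_raster, x, y), spec$floor_density)
  sd_m <- spec$c / dens
  draw <- function() c(x + rnorm(1, 0, sd_m), y + rnorm(1, 0, sd_m))
  res <- with_seed(spec$seed, {
    p <- draw()
    tries <- 1L
    while (!in_window(window, p[1], p[2]) && tries < 100L) {
      p <- draw()
      tries <- tries + 1L
    }
    list(p = p, tries = tries)
  })
  if (!in_window(window, res$p[1], res$p[2])) {
    abort("blurring failed: 100 draws fell outside the window (home in a sliver)")
  }
  list(x = res$p[1], y = res$p[2], sd_m = sd_m,
    displacement_m = sqrt((res$p[1] - x)^2 + (res$p[2] - y)^2))
}

#' @param c scale constant in m * residents/km^2; the default gives a median
#'   displacement of about 60 m at 4000 residents/km^2.
#' @param floor_density density floor applied before computing the SD.
#' @param seed integer seed making the draw reproducible.
#' @rdname blur_residence
#' @export
blur_spec <- function(c = 2e5, floor_density = 100, seed = 1L) {
  assert_scalar_pos(c, "c")
  structure(list(c = c, floor_density = floor_density, seed = seed),
    class = "kh_blur_spec")
}
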