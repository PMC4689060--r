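#' Street networks
#'
#' A street network is a planar graph with node coordinates in metres and
#' straight-line edges with metric lengths. The igraph representation (edge
#' weights = lengths) is carried along for shortest-path queries, together
#' with connected-component membership.
#'
#' @param nodes tibble with columns `id`, `x`, `y`.
#' @param edges tibble with columns `from`, `to` (node ids).
#' @param window a `kh_window` containing all nodes.
#' @return an object of class `kh_network`.
#' @export
street_network <- function(nodes, edges, window) {
  stopifnot(all(c("id", "x", "y") %in% names(nodes)),
    all(c("from", "to") %in% names(edges)),
    inherits(window, "kh_window"))
  if (!all(in_window(window, nodes$x, nodes$y))) {
    abort("all network nodes must lie inside the window")
  }
  nodes <- as_tibble(nodes[c("id", "x", "y")])
  idx <- match(c(edges$from, edges$to), nodes$id)
  if (anyNA(idx)) abort("edge endpoints must reference node ids")
  fi <- idx[seq_len(nrow(edges))]
  ti <- idx[nrow(edges) + seq_len(nrow(edges))]
  edges <- tibble(
    edge_id = seq_len(nrow(edges)),
    from = edges$from, to = edges$to,
    x1 = nodes$x[fi], y1 = nodes$y[fi],
    x2 = nodes$x[ti], y2 = nodes$y[ti]
  )
  edges$length_m <- sqrt((edges$x2 - edges$x1)^2 + (edges$y2 - edges$y1)^2)
  if (any(edges$length_m <= 0)) abort("every edge must have positive length")
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(edges$from), to = as.character(edges$to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$id))
  )
  igraph::E(g)$weight <- edges$length_m
  comp <- igraph::components(g)
  nodes$degree <- as.integer(igraph::degree(g)[as.character(nodes$id)])
  nodes$component <- as.integer(comp$membership[as.character(nodes$id)])
  structure(
    list(nodes = nodes, edges = edges, graph = g, window = window,
         n_components = comp$no,
         main_component_frac = max(comp$csize) / nrow(nodes)),
    class = "kh_network"
  )
}

#' @export
print.kh_network <- function(x, ...) {
  cat(sprintf(
    "<kh_network> %d nodes, %d edges, total length %.1f km (%d component%s, largest %.0f%%)\n",
    nrow(x$nodes), nrow(x$edges), sum(x$edges$length_m) / 1000,
    x$n_components, if (x$n_components == 1) "" else "s",
    100 * x$main_component_frac))
  invisible(x)
}

#' @export
tidy.kh_network <- function(x, ...) {
  x$edges
}

#' @export
autoplot.kh_network <- function(object, ...) {
  ggplot2::ggplot(object$edges) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2),
      linewidth = 0.3, colour = "grey30") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [m]", y = "y [m]")
}

#' Snap a location to the nearest network edge
#'
#' Returns the nearest point on any straight edge, the host edge id, the
#' arc-position along the edge, and the snap distance. Ties between edges are
#' broken deterministically toward the lowest edge id. A warning is issued
#' when the snap distance exceeds `warn_m` (the location lies far off the
#' network, e.g. in a rural periphery).
#'
#' @param x,y location coordinates (metres).
#' @param network a `kh_network`.
#' @param warn_m snap-distance warning threshold (metres, default 250).
#' @return a list with `edge_id`, `t` (metres along the edge from its `from`
#'   node), `x`, `y` (snapped coordinates), and `snap_dist_m`.
#' @export
snap_to_network <- function(x, y, network, warn_m = 250) {
  stopifnot(inherits(network, "kh_network"), length(x) == 1L)
  e <- network$edges
  d <- dist_point_segment(x, y, e$x1, e$y1, e$x2, e$y2)
  best <- which(d <= min(d) + 1e-9)[1] # lowest edge id on ties
  t <- proj_point_segment(x, y, e$x1[best], e$y1[best], e$x2[best], e$y2[best])
  L <- e$length_m[best]
  ux <- (e$x2[best] - e$x1[best]) / L
  uy <- (e$y2[best] - e$y1[best]) / L
  if (d[best] > warn_m) {
    warn(sprintf("snap distance %.0f m exceeds %.0f m; location is far from the network",
      d[best], warn_m))
  }
  list(
    edge_id = e$edge_id[best], t = t,
    x = e$x1[best] + t * ux, y = e$y1[best] + t * uy,
    snap_dist_m = d[best]
  )
}

# Shortest network distances from a (snapped) origin to all nodes, treating
# the origin as a virtual node splitting its host edge. Returns a numeric
# vector indexed like network$nodes.
node_distances_from <- function(network, origin) {
  e <- network$edges
  host <- e[e$edge_id == origin$edge_id, ]
  g <- network$graph
  a <- origin$t
  b <- host$length_m - a
  if (a < 1e-9) {
    d <- igraph::distances(g, v = as.character(host$from))[1, ]
  } else if (b < 1e-9) {
    d <- igraph::distances(g, v = as.character(host$to))[1, ]
  } else {
    g2 <- igraph::add_vertices(g, 1, name = "..origin..")
    g2 <- igraph::add_edges(g2,
      c("..origin..", as.character(host$from),
        "..origin..", as.character(host$to)),
      attr = list(weight = c(a, b)))
    d <- igraph::distances(g2, v = "..origin..")[1, ]
    d <- d[names(d) != "..origin.."]
  }
  unname(d[as.character(network$nodes$id)])
}
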