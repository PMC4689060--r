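# ---- per-child exposure assessment --------------------------------------

KH_MEASURES <- c("simple", "fixed", "fixed_adaptive", "mse_cv",
  "mse_cv_adaptive", "lscv", "lscv_adaptive")

KH_DISTANCES <- c(500, 750, 1000, 1250, 1500, 2000)

#' Exposure assessment settings
#'
#' @param distances network distances in metres (strictly increasing).
#' @param measures subset of the seven intensity measures: `simple`,
#'   `fixed`, `fixed_adaptive`, `mse_cv`, `mse_cv_adaptive`, `lscv`,
#'   `lscv_adaptive`.
#' @param buffer_m service-area buffer width (metres).
#' @param cell_size_m intensity-surface grid cell size (metres).
#' @param fixed_sigma_m fixed pilot bandwidth (metres).
#' @param blur apply privacy blurring to residences before snapping.
#' @param blur_c blurring scale constant (see [blur_spec()]).
#' @param pilot_density,floor_density adaptive-bandwidth pilot density and
#'   `R_A` floor (residents/km^2).
#' @param area_resolution_m fine-grid resolution for service-area areas
#'   (default `buffer_m / 2.5`, i.e. 10 m at the default buffer; the
#'   standalone [service_area()] uses the finer `buffer_m / 5`).
#' @param snap_warn_m children snapping farther than this from the network
#'   are flagged and skipped (off-network residence).
#' @param seed integer seed driving the blurring draws.
#' @return a `kh_exposure_config` list.
#' @export
exposure_config <- function(distances = KH_DISTANCES,
                            measures = KH_MEASURES,
                            buffer_m = 25,
                            cell_size_m = 25,
                            fixed_sigma_m = 500,
                            blur = TRUE,
                            blur_c = 2e5,
                            pilot_density = 2000,
                            floor_density = 100,
                            area_resolution_m = NULL,
                            snap_warn_m = 250,
                            seed = 1L) {
  if (any(diff(distances) <= 0) || any(distances <= 0)) {
    abort("distances must be positive and strictly increasing")
  }
  bad <- setdiff(measures, KH_MEASURES)
  if (length(bad)) {
    abort(sprintf("unknown measures: %s", paste(bad, collapse = ", ")))
  }
  structure(
    list(distances = distances, measures = measures, buffer_m = buffer_m,
      cell_size_m = cell_size_m, fixed_sigma_m = fixed_sigma_m,
      blur = blur, blur_c = blur_c, pilot_density = pilot_density,
      floor_density = floor_density,
      area_resolution_m = area_resolution_m %||% (buffer_m / 2.5),
      snap_warn_m = snap_warn_m, seed = as.integer(seed)),
    class = "kh_exposure_config"
  )
}

measure_parent <- function(measure) {
  switch(measure,
    fixed = , fixed_adaptive = "fixed",
    mse_cv = , mse_cv_adaptive = "mse_cv",
    lscv = , lscv_adaptive = "lscv",
    NULL)
}

# parent bandwidths per layer; selector failures drop the dependent
# measures for that layer (with a warning) rather than aborting the run
layer_bandwidths <- function(layers, config) {
  need <- unique(unlist(lapply(config$measures, measure_parent)))
  out <- list()
  for (kind in names(layers)) {
    bws <- list()
    if ("fixed" %in% need) {
      bws$fixed <- bw_fixed(config$fixed_sigma_m)
    }
    if ("mse_cv" %in% need) {
      bws$mse_cv <- tryCatch(bw_mse_cv(layers[[kind]],
        cell_size_m = config$cell_size_m)$bandwidth,
        error = function(e) {
          warn(sprintf("mse_cv selection failed for layer '%s': %s",
            kind, conditionMessage(e)))
          NULL
        })
    }
    if ("lscv" %in% need) {
      bws$lscv <- tryCatch({
        r <- bw_lscv_aniso(layers[[kind]])
        if (!r$converged) abort("no LSCV start converged")
        r$bandwidth
      }, error = function(e) {
        warn(sprintf("lscv selection failed for layer '%s': %s",
          kind, conditionMessage(e)))
        NULL
      })
    }
    out[[kind]] <- bws
  }
  out
}

#' Build the per-child exposure matrix
#'
#' For every child: (optionally) blur the residence, snap it to the street
#' network, construct the service areas at all configured distances, and
#' evaluate every configured intensity measure of every point layer inside
#' them. Non-adaptive kernel surfaces are computed once per layer; adaptive
#' variants are re-evaluated per child and distance with the bandwidth
#' scaled by `pilot_density / R_A`, where `R_A` is the mean residential
#' density over that child's service area. Any per-child failure (e.g. a
#' residence snapping farther than `snap_warn_m` from the network) is
#' logged and the child is skipped, not a crash.
#'
#' @param cohort child tibble with `child_id`, `home_x`, `home_y`.
#' @param layers named list of [point_pattern()]s
#'   (e.g. `intersections`, `transit`, `open_space`).
#' @param network a [street_network()].
#' @param density residents/km^2 `kh_raster`.
#' @param config an [exposure_config()].
#' @return tibble of exposure records (`child_id`, `kind`, `measure`,
#'   `distance_m`, `value` in points/km^2, `r_a`), with attributes
#'   `errors` (per-child failure log) and `bandwidths` (per-layer parent
#'   bandwidths).
#' @export
build_exposure_matrix <- function(cohort, layers, network, density,
                                  config = exposure_config()) {
  stopifnot(inherits(network, "kh_network"), inherits(density, "kh_raster"))
  stopifnot(is.list(layers), length(layers) > 0, !is.null(names(layers)))
  window <- network$window
  bws <- layer_bandwidths(layers, config)
  # non-adaptive surfaces, one per (layer, parent)
  surfaces <- list()
  for (kind in names(layers)) {
    surfaces[[kind]] <- list()
    for (p in unique(unlist(lapply(config$measures, measure_parent)))) {
      if (is.null(bws[[kind]][[p]])) next
      surfaces[[kind]][[p]] <- suppressWarnings(kernel_intensity_surface(
        layers[[kind]], bws[[kind]][[p]], cell_size_m = config$cell_size_m))
    }
  }
  sg <- list( # shared surface grid geometry
    gx = window$xmin + (seq_len(max(1L, round((window$xmax - window$xmin) / config$cell_size_m))) - 0.5) * config$cell_size_m,
    gy = window$ymin + (seq_len(max(1L, round((window$ymax - window$ymin) / config$cell_size_m))) - 0.5) * config$cell_size_m
  )
  records <- vector("list", nrow(cohort))
  errors <- list()
  for (ci in seq_len(nrow(cohort))) {
    rec <- tryCatch(
      child_exposure_records(
        child_id = cohort$child_id[ci],
        home = c(cohort$home_x[ci], cohort$home_y[ci]),
        layers = layers, network = network, density = density,
        surfaces = surfaces, bws = bws, sg = sg, config = config,
        window = window),
      error = function(e) e
    )
    if (inherits(rec, "error")) {
      errors[[length(errors) + 1L]] <- tibble(
        child_id = cohort$child_id[ci], stage = "exposure",
        message = conditionMessage(rec))
    } else {
      records[[ci]] <- rec
    }
  }
  out <- bind_rows(records)
  attr(out, "errors") <- bind_rows(errors)
  attr(out, "bandwidths") <- bws
  out
}

child_exposure_records <- function(child_id, home, layers, network, density,
                                   surfaces, bws, sg, config, window) {
  loc <- home
  if (config$blur) {
    b <- blur_residence(home[1], home[2], density,
      blur_spec(c = config$blur_c, floor_density = config$floor_density,
        seed = stream_seed(config$seed, paste0("blur_", child_id))),
      window = window)
    loc <- c(b$x, b$y)
  }
  origin <- withCallingHandlers(
    snap_to_network(loc[1], loc[2], network, warn_m = config$snap_warn_m),
    warning = function(w) invokeRestart("muffleWarning"))
  if (origin$snap_dist_m > config$snap_warn_m) {
    abort(sprintf("residence snaps %.0f m from the network (limit %.0f m)",
      origin$snap_dist_m, config$snap_warn_m))
  }
  dd <- origin_node_distances(network, origin)
  d_max <- max(config$distances)
  buffer <- config$buffer_m
  # only edges reachable within the largest distance can contribute
  keep_e <- which(pmin(dd$du, dd$dv, na.rm = FALSE) <= d_max |
    network$edges$edge_id == origin$edge_id)
  edges <- network$edges[keep_e, , drop = FALSE]
  du <- dd$du[keep_e]
  dv <- dd$dv[keep_e]
  frags_max <- reach_fragments(edges, du, dv, origin, d_max)
  if (nrow(frags_max) == 0L) abort("no network reachable from origin")
  xlo <- max(window$xmin, min(frags_max$x1, frags_max$x2) - buffer)
  xhi <- min(window$xmax, max(frags_max$x1, frags_max$x2) + buffer)
  ylo <- max(window$ymin, min(frags_max$y1, frags_max$y2) - buffer)
  yhi <- min(window$ymax, max(frags_max$y1, frags_max$y2) + buffer)
  need_adaptive <- any(grepl("_adaptive$", config$measures))
  need_fine <- need_adaptive || "simple" %in% config$measures
  if (need_fine) {
    # fine grid over the maximal footprint: one reach evaluation serves
    # every distance (masks are nested in the reach value)
    res <- config$area_resolution_m
    fgx <- seq(xlo + res / 2, xhi, by = res)
    fgy <- seq(ylo + res / 2, yhi, by = res)
    Rfine <- reach_grid(fgx, fgy, edges, du, dv, origin, buffer)
    fcx <- rep(fgx, each = length(fgy))
    fcy <- rep(fgy, times = length(fgx))
  }
  # surface-grid reach (shared by all layers and parents), restricted to
  # the service-area bounding box
  ix <- which(sg$gx >= xlo - buffer & sg$gx <= xhi + buffer)
  iy <- which(sg$gy >= ylo - buffer & sg$gy <= yhi + buffer)
  Rsurf <- reach_grid(sg$gx[ix], sg$gy[iy], edges, du, dv, origin, buffer)
  scx <- rep(sg$gx[ix], each = length(iy))
  scy <- rep(sg$gy[iy], times = length(ix))
  # matching linear indices into the [ny, nx] surface value matrices
  surf_idx <- as.vector(outer(iy, (ix - 1L) * length(sg$gy), "+"))
  # per-layer point reach (distances to origin along the network)
  layer_reach <- lapply(layers, function(p) {
    if (npoints(p) == 0L) return(numeric(0))
    reach_points(p$x, p$y, edges, du, dv, origin, buffer)
  })
  n_rows <- length(config$distances) * length(layers) * length(config$measures)
  acc <- list(kind = character(n_rows), measure = character(n_rows),
    distance_m = numeric(n_rows), value = rep(NA_real_, n_rows),
    r_a = rep(NA_real_, n_rows), keep = logical(n_rows))
  ptr <- 0L
  for (D in config$distances) {
    area_km2 <- NA_real_
    r_a <- NA_real_
    if (need_fine) {
      sel <- which(as.vector(Rfine) <= D)
      area_km2 <- length(sel) * res^2 / 1e6
      r_a <- if (length(sel)) {
        mean(raster_at(density, fcx[sel], fcy[sel]))
      } else {
        raster_at(density, origin$x, origin$y)
      }
    }
    surf_sel <- which(as.vector(Rsurf) <= D)
    for (kind in names(layers)) {
      pat <- layers[[kind]]
      for (m in config$measures) {
        val <- NA_real_
        ra_out <- NA_real_
        ok <- TRUE
        if (m == "simple") {
          if (area_km2 <= 0) abort("zero-area service area")
          val <- sum(layer_reach[[kind]] <= D) / area_km2
        } else if (m %in% c("fixed", "mse_cv", "lscv")) {
          surf <- surfaces[[kind]][[m]]
          if (is.null(surf)) {
            ok <- FALSE
          } else {
            val <- if (length(surf_sel)) {
              mean(surf$values[surf_idx[surf_sel]])
            } else {
              surface_at(surf, origin$x, origin$y)
            }
          }
        } else {
          parent <- measure_parent(m)
          pbw <- bws[[kind]][[parent]]
          if (is.null(pbw)) {
            ok <- FALSE
          } else {
            abw <- adaptive_scale(pbw, r_a,
              pilot_density = config$pilot_density,
              floor_density = config$floor_density)
            ex <- if (length(surf_sel)) scx[surf_sel] else origin$x
            ey <- if (length(surf_sel)) scy[surf_sel] else origin$y
            wts <- if (npoints(pat) > 0) {
              edge_correction(pat$x, pat$y, abw, window)
            }
            ks <- kernel_sum(ex, ey, pat$x, pat$y, bw_cov(abw), wts = wts)
            val <- mean(ks) * 1e6
            ra_out <- r_a
          }
        }
        ptr <- ptr + 1L
        acc$kind[ptr] <- kind
        acc$measure[ptr] <- m
        acc$distance_m[ptr] <- D
        acc$value[ptr] <- val
        acc$r_a[ptr] <- ra_out
        acc$keep[ptr] <- ok
      }
    }
  }
  sel <- which(acc$keep[seq_len(ptr)])
  tibble(
    child_id = child_id, kind = acc$kind[sel], measure = acc$measure[sel],
    distance_m = acc$distance_m[sel], value = acc$value[sel],
    r_a = acc$r_a[sel]
  )
}

#' Summary of exposure records by measure and distance
#'
#' Mean and SD of each measure across children per layer kind and network
#' distance (the descriptive summary of the exposure assessment).
#'
#' @param exposures output of [build_exposure_matrix()].
#' @return tibble with `kind`, `measure`, `distance_m`, `mean`, `sd`, `n`.
#' @export
exposure_summary <- function(exposures) {
  exposures |>
    group_by(.data$kind, .data$measure, .data$distance_m) |>
    summarise(mean = mean(.data$value), sd = sd(.data$value),
      n = dplyr::n(), .groups = "drop")
}
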