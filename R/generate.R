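# ---- synthetic study region generators ----------------------------------

#' Generate a synthetic street network
#'
#' Builds a rectangular street lattice at the configured block spacing and
#' removes a random fraction of edges. The dropout is redrawn (up to 20
#' times) until the largest connected component keeps at least 90% of the
#' nodes; a configuration that cannot satisfy this is rejected.
#'
#' @param config a [city_config()].
#' @return a [street_network()].
#' @examples
#' net <- generate_street_network(city_config(
#'   window_width_m = 1000, window_height_m = 1000,
#'   grid_spacing_m = 100, edge_dropout_frac = 0))
#' nrow(net$nodes) # 121 nodes of an 11 x 11 lattice
#' @export
generate_street_network <- function(config) {
  stopifnot(inherits(config, "kh_city_config"))
  window <- window_rect(config$window_width_m, config$window_height_m)
  s <- config$grid_spacing_m
  xs <- seq(0, config$window_width_m, by = s)
  ys <- seq(0, config$window_height_m, by = s)
  nxn <- length(xs)
  nyn <- length(ys)
  nodes <- tibble(
    id = seq_len(nxn * nyn),
    x = rep(xs, times = nyn),
    y = rep(ys, each = nxn)
  )
  node_at <- function(ix, iy) (iy - 1L) * nxn + ix
  hor <- tibble(
    from = node_at(rep(seq_len(nxn - 1L), times = nyn), rep(seq_len(nyn), each = nxn - 1L)),
    to = node_at(rep(seq_len(nxn - 1L), times = nyn) + 1L, rep(seq_len(nyn), each = nxn - 1L))
  )
  ver <- tibble(
    from = node_at(rep(seq_len(nxn), times = nyn - 1L), rep(seq_len(nyn - 1L), each = nxn)),
    to = node_at(rep(seq_len(nxn), times = nyn - 1L), rep(seq_len(nyn - 1L), each = nxn) + 1L)
  )
  edges <- bind_rows(hor, ver)
  n_drop <- round(config$edge_dropout_frac * nrow(edges))
  if (n_drop == 0L) {
    return(street_network(nodes, edges, window))
  }
  for (try in seq_len(20L)) {
    keep <- with_seed(stream_seed(config$seed, paste0("network", try)), {
      sort(sample(nrow(edges), nrow(edges) - n_drop))
    })
    net <- street_network(nodes, edges[keep, ], window)
    if (net$main_component_frac >= 0.9) {
      return(net)
    }
  }
  abort("edge dropout disconnects the network beyond the 90% rule; lower edge_dropout_frac")
}

#' Generate the residential-density gradient
#'
#' A truncated anisotropic Gaussian gradient centred on the window: density
#' falls from `density_peak` at the centre toward `density_floor`, with
#' elliptical isocontours of the configured anisotropy ratio (major axis
#' along x). The minor-axis scale is a quarter of the smaller window extent.
#'
#' @param config a [city_config()].
#' @return a `kh_raster` of residents/km^2 with attribute
#'   `total_residents`.
#' @export
generate_density_raster <- function(config) {
  stopifnot(inherits(config, "kh_city_config"))
  cell <- config$density_cell_m
  nx <- max(1L, round(config$window_width_m / cell))
  ny <- max(1L, round(config$window_height_m / cell))
  cxs <- (seq_len(nx) - 0.5) * cell
  cys <- (seq_len(ny) - 0.5) * cell
  mx <- config$window_width_m / 2
  my <- config$window_height_m / 2
  b <- min(config$window_width_m, config$window_height_m) / 4
  a <- b * config$anisotropy_ratio
  dx <- matrix(rep(cxs, each = ny), ny, nx) - mx
  dy <- matrix(rep(cys, times = nx), ny, nx) - my
  q <- (dx / a)^2 + (dy / b)^2
  vals <- config$density_floor_residents_km2 +
    (config$density_peak_residents_km2 - config$density_floor_residents_km2) *
      exp(-0.5 * q * 4) # scaled so density decays to near-floor at the rim
  r <- kh_raster(vals, origin = c(0, 0), cell_size_m = cell,
    units = "residents/km^2")
  attr(r, "total_residents") <- raster_total_residents(r)
  r
}

#' Generate a point layer of urban characteristics
#'
#' Intersections are the network nodes of degree >= 3 (the standard GIS
#' convention). The sampled kinds (`transit`, `open_space`) are drawn from an
#' inhomogeneous Poisson process with intensity proportional to residential
#' density, with expected count `points_per_1000_residents * total residents
#' / 1000`; a positive `layer_clustering` switches to a Neyman-Scott
#' construction (density-placed parents with `1 + clustering` expected
#' offspring scattered around them).
#'
#' @param kind `"intersections"`, `"transit"`, or `"open_space"`.
#' @param density a [generate_density_raster()] output.
#' @param network a [generate_street_network()] output.
#' @param config a [city_config()].
#' @return a [point_pattern()].
#' @export
generate_point_layer <- function(kind, density, network, config) {
  stopifnot(inherits(config, "kh_city_config"))
  window <- network$window
  if (kind == "intersections") {
    sel <- network$nodes$degree >= 3L
    return(point_pattern(network$nodes$x[sel], network$nodes$y[sel],
      window, kind = "intersections"))
  }
  rate <- config$points_per_1000_residents[[kind]]
  if (is.null(rate)) abort(sprintf("no points_per_1000_residents entry for '%s'", kind))
  total <- raster_total_residents(density)
  expected <- rate * total / 1000
  clustering <- config$layer_clustering[[kind]] %||% 0
  pts <- with_seed(stream_seed(config$seed, paste0("layer_", kind)), {
    sample_density_points(density, expected, clustering,
      cluster_sd = config$grid_spacing_m / 2, window)
  })
  if (nrow(pts) == 0L && expected >= 1) {
    warn(sprintf("layer '%s' came out empty despite expected count %.1f", kind, expected))
  }
  point_pattern(pts$x, pts$y, window, kind = kind)
}

# draw points with intensity proportional to the density raster; total count
# Poisson(expected); clustering > 0 uses a Neyman-Scott parent/offspring
# construction preserving the expected count
sample_density_points <- function(density, expected, clustering, cluster_sd,
                                  window) {
  draw_base <- function(n) {
    if (n == 0L) {
      return(tibble(x = numeric(0), y = numeric(0)))
    }
    w <- as.vector(density$values)
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    iy <- ((idx - 1L) %% density$ny) + 1L
    ix <- ((idx - 1L) %/% density$ny) + 1L
    tibble(
      x = density$x0 + (ix - 1L + runif(n)) * density$cell_size_m,
      y = density$y0 + (iy - 1L + runif(n)) * density$cell_size_m
    )
  }
  if (clustering <= 0) {
    return(draw_base(rpois(1, expected)))
  }
  mean_size <- 1 + clustering
  parents <- draw_base(rpois(1, expected / mean_size))
  if (nrow(parents) == 0L) {
    return(parents)
  }
  sizes <- 1L + rpois(nrow(parents), clustering)
  px <- rep(parents$x, sizes)
  py <- rep(parents$y, sizes)
  n <- length(px)
  x <- px + rnorm(n, 0, cluster_sd)
  y <- py + rnorm(n, 0, cluster_sd)
  # clamp offspring into the window (cluster scatter near the rim)
  x <- pmin(window$xmax, pmax(window$xmin, x))
  y <- pmin(window$ymax, pmax(window$ymin, y))
  tibble(x = x, y = y)
}

# truncated-normal helper
rnorm_trunc <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  guard <- 0L
  while (length(bad) > 0 && guard < 50L) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    guard <- guard + 1L
  }
  pmin(hi, pmax(lo, x))
}

#' Generate a synthetic child cohort with known ground truth
#'
#' Samples home locations proportional to residential density, draws
#' individual covariates from the configured stratum marginals, evaluates
#' the true exposure at each home, and draws habitual MVPA from
#' `Gamma(shape = nu, mean = exp(X beta))` using the configured `true_beta`.
#' The returned truth object retains everything needed to recompute each
#' child's linear predictor exactly.
#'
#' @param config a [cohort_config()].
#' @param density a residents/km^2 `kh_raster`.
#' @param truth_exposure_fn function `(x, y) -> exposure` mapping a home
#'   location to the true exposure entering the linear predictor, or NULL
#'   for no exposure term.
#' @param window a `kh_window` (defaults to the raster extent).
#' @return list with `cohort` (tibble of child records) and `truth`
#'   (the realized inputs: per-child linear predictors, `true_beta`, seeds).
#' @export
generate_cohort <- function(config, density, truth_exposure_fn = NULL,
                            window = NULL) {
  stopifnot(inherits(config, "kh_cohort_config"), inherits(density, "kh_raster"))
  n <- config$n_children
  if (n < 10) {
    warn("cohorts below 10 children are too small for model fitting; returned for unit testing only")
  }
  if (is.null(window)) {
    window <- window_rect(density$nx * density$cell_size_m,
      density$ny * density$cell_size_m,
      origin = c(density$x0, density$y0))
  }
  cohort <- with_seed(stream_seed(config$seed, "cohort"), {
    w <- as.vector(density$values)
    idx <- sample.int(length(w), n, replace = TRUE, prob = w)
    iy <- ((idx - 1L) %% density$ny) + 1L
    ix <- ((idx - 1L) %/% density$ny) + 1L
    home_x <- density$x0 + (ix - 1L + runif(n)) * density$cell_size_m
    home_y <- density$y0 + (iy - 1L + runif(n)) * density$cell_size_m
    age_group <- ifelse(rbinom(n, 1, config$frac_school_age) == 1L,
      "school", "preschool")
    sex <- ifelse(rbinom(n, 1, config$frac_girls) == 1L, "girl", "boy")
    age <- ifelse(age_group == "school",
      rnorm_trunc(n, 7.5, 0.8, 6, 9.9),
      rnorm_trunc(n, 4.2, 0.85, 2, 5.999))
    bmi_z <- ifelse(age_group == "school",
      rnorm(n, 0.42, 1.05), rnorm(n, 0.03, 1.15))
    isced <- vapply(age_group, function(g) {
      p <- config$isced_probs[[if (g == "school") "school" else "preschool"]]
      sample(names(p), 1, prob = p)
    }, character(1))
    stratum <- paste0(ifelse(age_group == "school", "school_", "preschool_"),
      ifelse(sex == "girl", "girls", "boys"))
    safety <- ifelse(rbinom(n, 1, config$safety_probs[stratum]) == 1L, "yes", "no")
    season <- ifelse(rbinom(n, 1, config$season_spring_summer_prob) == 1L,
      "spring_summer", "autumn_winter")
    weartime <- rnorm_trunc(n, config$weartime_mean_h, config$weartime_sd_h, 8, 16)
    tibble(
      child_id = sprintf("c%04d", seq_len(n)),
      home_x = home_x, home_y = home_y,
      age_group = age_group, sex = sex, age_years = age, bmi_z = bmi_z,
      isced = isced, safety_concerns = safety, season = season,
      valid_weartime_h = weartime
    )
  })
  exposure <- if (is.null(truth_exposure_fn)) {
    rep(0, n)
  } else {
    vapply(seq_len(n), function(i) {
      truth_exposure_fn(cohort$home_x[i], cohort$home_y[i])
    }, numeric(1))
  }
  cohort$true_exposure <- exposure
  eta <- vapply(seq_len(n), function(i) {
    b <- config$true_beta[[if (cohort$age_group[i] == "school") "school" else "preschool"]]
    b[["intercept"]] +
      b[["age"]] * cohort$age_years[i] +
      b[["bmi_z"]] * cohort$bmi_z[i] +
      b[["weartime"]] * cohort$valid_weartime_h[i] +
      b[["season_spring_summer"]] * (cohort$season[i] == "spring_summer") +
      b[["safety_yes"]] * (cohort$safety_concerns[i] == "yes") +
      b[["isced_low"]] * (cohort$isced[i] == "low") +
      b[["isced_high"]] * (cohort$isced[i] == "high") +
      b[["exposure"]] * exposure[i]
  }, numeric(1))
  mvpa <- with_seed(stream_seed(config$seed, "mvpa"), {
    rgamma(n, shape = config$gamma_shape, rate = config$gamma_shape / exp(eta))
  })
  cohort$mvpa_min_per_day <- mvpa
  truth <- list(
    linear_predictor = eta,
    true_exposure = exposure,
    true_beta = config$true_beta,
    gamma_shape = config$gamma_shape,
    seeds = c(cohort = stream_seed(config$seed, "cohort"),
      mvpa = stream_seed(config$seed, "mvpa"))
  )
  list(cohort = cohort, truth = truth)
}

#' Epoch-count generation settings
#'
#' @param wear_start_hour,wear_end_hour daily wear window (device worn
#'   between these hours).
#' @param noise `"none"` for the deterministic construction (exact
#'   round-trip) or `"poisson"` for jittered counts.
#' @param nonwear_bouts list of `list(day, start_hour, duration_min)` zero
#'   runs injected into the series.
#' @param mvpa_count,light_count epoch counts used for MVPA-level and
#'   light-level epochs in the deterministic mode.
#' @param seed integer seed for the stochastic mode.
#' @return a `kh_epoch_config` list.
#' @export
epoch_config <- function(wear_start_hour = 7, wear_end_hour = 21,
                         noise = c("none", "poisson"),
                         nonwear_bouts = list(),
                         mvpa_count = 1000, light_count = 100,
                         seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(wear_end_hour > wear_start_hour)
  structure(
    list(wear_start_hour = wear_start_hour, wear_end_hour = wear_end_hour,
      noise = noise, nonwear_bouts = nonwear_bouts,
      mvpa_count = mvpa_count, light_count = light_count,
      seed = as.integer(seed)),
    class = "kh_epoch_config"
  )
}

#' Generate a 15-second epoch series for one child
#'
#' Emits counts at 15-s resolution over `n_days` inside a diurnal wear
#' window, with optional injected non-wear bouts (runs of zeros) and
#' MVPA-level epochs whose expected daily total equals
#' `habitual_mvpa_min_per_day`. In the deterministic `"none"` noise mode the
#' daily MVPA total is exact, so the accelerometry module recovers the
#' configured value to the epoch.
#'
#' @param child_id identifier.
#' @param habitual_mvpa_min_per_day target MVPA minutes per day.
#' @param n_days number of consecutive days.
#' @param start_date first day (a `Date`; its weekday drives the weekend
#'   rule).
#' @param config an [epoch_config()].
#' @return tibble with `child_id`, `timestamp`, `date`, `weekday`, `counts`.
#' @export
generate_epoch_counts <- function(child_id, habitual_mvpa_min_per_day,
                                  n_days = 7,
                                  start_date = as.Date("2007-10-01"),
                                  config = epoch_config()) {
  stopifnot(inherits(config, "kh_epoch_config"))
  wear_min <- (config$wear_end_hour - config$wear_start_hour) * 60
  if (habitual_mvpa_min_per_day > wear_min) {
    abort("habitual MVPA exceeds the daily wear window")
  }
  n_epoch_day <- wear_min * 4L
  days <- start_date + seq_len(n_days) - 1L
  build_day <- function(d, day_index) {
    secs <- seq(config$wear_start_hour * 3600,
      by = 15, length.out = n_epoch_day)
    counts <- rep(config$light_count, n_epoch_day)
    nonwear <- rep(FALSE, n_epoch_day)
    for (b in config$nonwear_bouts) {
      if (b$day != day_index) next
      i0 <- round((b$start_hour - config$wear_start_hour) * 240) + 1L
      i1 <- min(n_epoch_day, i0 + round(b$duration_min * 4) - 1L)
      if (i0 >= 1 && i0 <= n_epoch_day) nonwear[i0:i1] <- TRUE
    }
    worn_idx <- which(!nonwear)
    n_mvpa <- round(habitual_mvpa_min_per_day * 4)
    if (n_mvpa > length(worn_idx)) {
      abort("habitual MVPA exceeds the worn part of the wear window")
    }
    if (config$noise == "none") {
      pick <- if (n_mvpa == 0L) {
        integer(0)
      } else {
        worn_idx[round(seq(1, length(worn_idx), length.out = n_mvpa))]
      }
      counts[pick] <- config$mvpa_count
    } else {
      p <- n_mvpa / length(worn_idx)
      is_mvpa <- rbinom(length(worn_idx), 1, min(1, p)) == 1L
      counts[worn_idx] <- ifelse(is_mvpa,
        575 + rpois(length(worn_idx), config$mvpa_count - 575),
        rpois(length(worn_idx), config$light_count))
    }
    counts[nonwear] <- 0L
    tibble(
      child_id = child_id,
      timestamp = as.POSIXct(d, tz = "UTC") + secs,
      date = d,
      weekday = weekday_label(d),
      counts = as.integer(counts)
    )
  }
  if (config$noise == "none") {
    bind_rows(lapply(seq_along(days), function(i) build_day(days[i], i)))
  } else {
    with_seed(stream_seed(config$seed, paste0("epochs_", child_id)), {
      bind_rows(lapply(seq_along(days), function(i) build_day(days[i], i)))
    })
  }
}
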