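# snapping, service areas, neighborhood aggregation, blurring

test_that("snapping returns nodes, perpendicular feet and deterministic ties", {
  net <- line_network()
  # exactly on a node
  s1 <- snap_to_network(500, 2000, net)
  expect_equal(s1$snap_dist_m, 0)
  expect_equal(s1$t, 0)
  # 10 m perpendicular from the midpoint
  s2 <- snap_to_network(2000, 2010, net)
  expect_equal(s2$snap_dist_m, 10)
  expect_equal(c(s2$x, s2$y), c(2000, 2000))
  # tie between two parallel edges resolved to the lowest edge id
  w <- window_rect(1000, 1000)
  two <- street_network(
    data.frame(id = 1:4, x = c(0, 1000, 0, 1000), y = c(400, 400, 600, 600)),
    data.frame(from = c(1, 3), to = c(2, 4)), w)
  tie <- snap_to_network(500, 500, two)
  expect_equal(tie$edge_id, 1L)
  # far locations warn
  expect_warning(snap_to_network(2000, 3900, line_network()), "snap distance")
})

test_that("straight-line service areas match closed-form geometry", {
  net <- line_network()
  sa <- service_area(net, c(2000, 2000), 500)
  expect_equal(sa$reached_length_m, 1000)
  analytic <- (1000 * 2 * 25 + pi * 25^2) / 1e6
  expect_lt(abs(sa$area_km2 - analytic) / analytic, 0.01)
  # wider buffer
  sa2 <- service_area(net, c(2000, 2000), 300, buffer_m = 50)
  analytic2 <- (600 * 2 * 50 + pi * 50^2) / 1e6
  expect_lt(abs(sa2$area_km2 - analytic2) / analytic2, 0.01)
})

test_that("service areas nest across the six study distances", {
  city <- small_city()
  o <- snap_to_network(1400, 1600, city$net)
  dists <- c(500, 750, 1000, 1250, 1500, 2000)
  sas <- lapply(dists, function(d) service_area(city$net, o, d))
  areas <- vapply(sas, function(s) s$area_km2, numeric(1))
  lens <- vapply(sas, function(s) s$reached_length_m, numeric(1))
  expect_true(all(diff(areas) > 0))
  expect_true(all(diff(lens) > 0))
  # fragment sets nest: every shorter-distance fragment lies inside the
  # longer-distance fragment set of the same edge
  for (k in 1:5) {
    a <- sas[[k]]$fragments
    b <- sas[[k + 1]]$fragments
    for (i in seq_len(nrow(a))) {
      hit <- b[b$edge_id == a$edge_id[i], ]
      expect_true(any(hit$t0 <= a$t0[i] + 1e-9 & hit$t1 >= a$t1[i] - 1e-9))
    }
  }
  # point membership is monotone in distance
  px <- runif(50, 0, 3000)
  py <- runif(50, 0, 3000)
  m1 <- kernelhoods:::sa_contains(sas[[1]], px, py)
  m6 <- kernelhoods:::sa_contains(sas[[6]], px, py)
  expect_true(all(m6[m1]))
})

test_that("reached fragment lengths match a brute-force shortest-path oracle", {
  # random 50-node graph; oracle = Floyd-Warshall in plain R
  set.seed(77)
  n <- 50
  nodes <- data.frame(id = 1:n, x = runif(n, 0, 2000), y = runif(n, 0, 2000))
  edges <- unique(data.frame(
    from = sample(n, 120, replace = TRUE),
    to = sample(n, 120, replace = TRUE)))
  edges <- edges[edges$from != edges$to, ]
  net <- street_network(nodes, edges, window_rect(2000, 2000))
  Dm <- matrix(Inf, n, n)
  diag(Dm) <- 0
  for (i in seq_len(nrow(net$edges))) {
    f <- net$edges$from[i]; t <- net$edges$to[i]; l <- net$edges$length_m[i]
    Dm[f, t] <- min(Dm[f, t], l)
    Dm[t, f] <- min(Dm[t, f], l)
  }
  for (k in 1:n) for (i in 1:n) {
    relax <- Dm[i, k] + Dm[k, ]
    Dm[i, ] <- pmin(Dm[i, ], relax)
  }
  origin_node <- net$nodes$id[which.max(net$nodes$degree)]
  o <- snap_to_network(net$nodes$x[net$nodes$id == origin_node],
    net$nodes$y[net$nodes$id == origin_node], net)
  D <- 800
  sa <- suppressWarnings(service_area(net, o, D))
  # oracle reached length per edge from node distances
  oracle_len <- 0
  dor <- Dm[origin_node, ]
  for (i in seq_len(nrow(net$edges))) {
    l <- net$edges$length_m[i]
    d1 <- dor[net$edges$from[i]]; d2 <- dor[net$edges$to[i]]
    a <- max(0, min(l, D - d1))
    b <- max(0, min(l, D - d2))
    oracle_len <- oracle_len + min(l, a + b)
  }
  expect_equal(sa$reached_length_m, oracle_len, tolerance = 1e-6)
})

test_that("isolated origins are flagged", {
  w <- window_rect(1000, 1000)
  net <- street_network(
    data.frame(id = 1:4, x = c(0, 30, 500, 1000), y = c(500, 500, 900, 900)),
    data.frame(from = c(1, 3), to = c(2, 4)), w)
  expect_warning(service_area(net, c(10, 500), 1000), "isolated origin")
})

test_that("residential density aggregation is an area-weighted raster mean", {
  net <- line_network()
  sa <- service_area(net, c(2000, 2000), 500)
  # constant raster
  flat <- kh_raster(matrix(2000, 40, 40), cell_size_m = 100)
  expect_equal(residential_density_in(sa, flat), 2000)
  # two halves: x < 2000 -> 1000, x >= 2000 -> 3000; the service area is
  # symmetric about x = 2000, so the weighted mean is 2000
  half <- kh_raster(cbind(matrix(1000, 40, 20), matrix(3000, 40, 20)),
    cell_size_m = 100)
  expect_equal(residential_density_in(sa, half), 2000, tolerance = 0.01)
  # irregular polygon vs Monte-Carlo integration oracle
  city <- small_city()
  o <- snap_to_network(1000, 1900, city$net)
  sa2 <- service_area(city$net, o, 750)
  got <- residential_density_in(sa2, city$dens)
  mc <- with_test_seed(99, {
    bx <- runif(1e5, 0, 3000)
    by <- runif(1e5, 0, 3000)
    inside <- kernelhoods:::sa_contains(sa2, bx, by)
    mean(raster_at(city$dens, bx[inside], by[inside]))
  })
  expect_lt(abs(got - mc) / mc, 0.02)
})

test_that("mean intensity over an area averages surface cells with fallback", {
  net <- line_network()
  sa <- service_area(net, c(2000, 2000), 500)
  # constant surface
  p <- point_pattern(numeric(0), numeric(0), net$window)
  s <- kernel_intensity_surface(p, bw_iso(300))
  s$values[] <- 5
  expect_equal(mean_intensity_in(sa, s), 5)
  # full window identity
  city <- small_city()
  surf <- suppressWarnings(kernel_intensity_surface(city$layers$open_space, bw_fixed(500)))
  o <- snap_to_network(1500, 1500, city$net)
  # linear gradient surface over the window: analytic mean over the area
  grad <- s
  gxs <- grad$x0 + (seq_len(grad$nx) - 0.5) * grad$cell_size_m
  grad$values <- matrix(rep(gxs, each = grad$ny) / 100, grad$ny, grad$nx)
  got <- mean_intensity_in(sa, grad)
  # the straight-line area is symmetric about x = 2000 -> mean = 20
  expect_equal(got, 20, tolerance = 0.01 * 20)
  # tiny area: no surface cell centre inside -> bilinear fallback, flagged
  tiny <- suppressWarnings(service_area(net, c(2000, 2000), 3, buffer_m = 2))
  val <- mean_intensity_in(tiny, grad)
  expect_true(isTRUE(attr(val, "fallback")))
  expect_equal(as.numeric(val), 20, tolerance = 0.05 * 20)
})

test_that("blurring shrinks with density, stays in the window, and is seeded", {
  city <- small_city()
  sp <- blur_spec(seed = 123L)
  b1 <- blur_residence(1500, 1500, city$dens, sp)
  b2 <- blur_residence(1500, 1500, city$dens, sp)
  expect_equal(c(b1$x, b1$y), c(b2$x, b2$y))
  # displacement -> 0 as density -> infinity
  dense <- kh_raster(matrix(1e9, 30, 30), cell_size_m = 100)
  b3 <- blur_residence(1500, 1500, dense, sp)
  expect_lt(b3$displacement_m, 0.1)
  # median displacement at peak density lands in the 50-100 m band
  disp <- vapply(1:1000, function(i) {
    blur_residence(1500, 1500, city$dens,
      blur_spec(seed = 5000L + i))$displacement_m
  }, numeric(1))
  expect_gte(median(disp), 50)
  expect_lte(median(disp), 100)
})

test_that("exposure records are complete and adaptive measures match parents in a flat city", {
  cfg <- city_config(window_width_m = 1500, window_height_m = 1500,
    grid_spacing_m = 150, density_peak_residents_km2 = 2000,
    density_floor_residents_km2 = 2000, seed = 2L)
  net <- generate_street_network(cfg)
  dens <- generate_density_raster(cfg)
  layers <- list(open_space = generate_point_layer("open_space", dens, net, cfg))
  co <- suppressWarnings(generate_cohort(
    cohort_config(n_children = 8, seed = 4L), dens)$cohort)
  ex <- suppressWarnings(build_exposure_matrix(co, layers, net, dens,
    exposure_config(measures = c("simple", "fixed", "fixed_adaptive",
      "mse_cv", "mse_cv_adaptive", "lscv", "lscv_adaptive"),
    distances = c(500, 1000), seed = 7L)))
  # one record per (child, kind, measure, distance)
  expect_equal(nrow(ex), 8 * 1 * 7 * 2)
  expect_equal(nrow(dplyr::distinct(ex, child_id, kind, measure, distance_m)),
    nrow(ex))
  # at exactly the pilot density every adaptive record equals its parent
  wide <- tidyr::pivot_wider(ex, id_cols = c("child_id", "distance_m"),
    names_from = "measure", values_from = "value")
  expect_equal(wide$fixed_adaptive, wide$fixed, tolerance = 1e-9)
  expect_equal(wide$mse_cv_adaptive, wide$mse_cv, tolerance = 1e-9)
  expect_equal(wide$lscv_adaptive, wide$lscv, tolerance = 1e-9)
  expect_true(all(ex$r_a[grepl("adaptive", ex$measure)] == 2000))
})

test_that("children snapping beyond the limit are skipped with a log entry", {
  net <- line_network()
  dens <- kh_raster(matrix(2000, 40, 40), cell_size_m = 100)
  lay <- list(points = point_pattern(c(1000, 2500), c(2000, 2000),
    net$window, "points"))
  co <- tibble::tibble(child_id = c("a", "b"),
    home_x = c(2000, 2000), home_y = c(2050, 3600))
  ex <- suppressWarnings(build_exposure_matrix(co, lay, net, dens,
    exposure_config(measures = "simple", distances = 500, blur = FALSE)))
  expect_equal(unique(ex$child_id), "a")
  err <- attr(ex, "errors")
  expect_equal(err$child_id, "b")
  expect_match(err$message, "snaps")
})

test_that("blurring perturbs but does not rewrite exposures at 1000 m and beyond", {
  # at the study-region density profile most homes lie in areas dense
  # enough that the displacement stays below ~100 m
  cfg <- city_config(seed = 6L)
  net <- generate_street_network(cfg)
  dens <- generate_density_raster(cfg)
  lay <- list(open_space = generate_point_layer("open_space", dens, net, cfg))
  co <- suppressWarnings(generate_cohort(
    cohort_config(n_children = 40, seed = 31L), dens)$cohort)
  exb <- suppressWarnings(build_exposure_matrix(co, lay, net, dens,
    exposure_config(measures = "fixed", distances = c(1000, 1500),
      blur = TRUE, seed = 11L)))
  exn <- suppressWarnings(build_exposure_matrix(co, lay, net, dens,
    exposure_config(measures = "fixed", distances = c(1000, 1500),
      blur = FALSE, seed = 11L)))
  j <- dplyr::inner_join(exb, exn, by = c("child_id", "kind", "measure", "distance_m"))
  for (d in c(1000, 1500)) {
    sub <- j[j$distance_m == d, ]
    expect_gt(cor(sub$value.x, sub$value.y), 0.9)
  }
})

test_that("exposure summaries show the variance patterns of the measures", {
  city <- small_city()
  co <- suppressWarnings(generate_cohort(
    cohort_config(n_children = 50, seed = 21L), city$dens)$cohort)
  ex <- suppressWarnings(build_exposure_matrix(co, city$layers, city$net,
    city$dens, exposure_config(measures = c("simple", "fixed", "lscv"),
      distances = c(500, 1000, 2000), seed = 3L)))
  s <- exposure_summary(ex)
  for (k in unique(s$kind)) {
    simple <- s[s$kind == k & s$measure == "simple", ]
    # simple-intensity SD shrinks from 500 m to 2000 m
    expect_gt(simple$sd[simple$distance_m == 500],
      simple$sd[simple$distance_m == 2000])
    # kernel-measure SDs at 500 m do not exceed the simple-intensity SD
    at500 <- s[s$kind == k & s$distance_m == 500, ]
    expect_true(all(at500$sd[at500$measure != "simple"] <=
      at500$sd[at500$measure == "simple"]))
  }
})
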