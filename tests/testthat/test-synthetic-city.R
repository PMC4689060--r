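# street-network, density and point-layer generators

test_that("a zero-dropout grid is a full lattice with exact edge lengths", {
  net <- generate_street_network(lattice_city_config())
  expect_equal(nrow(net$nodes), 121)
  expect_equal(nrow(net$edges), 220)
  expect_true(all(abs(net$edges$length_m - 100) < 1e-9))
  expect_true(all(in_window(net$window, net$nodes$x, net$nodes$y)))
})

test_that("network generation is deterministic under a fixed seed", {
  cfg <- lattice_city_config(seed = 7L, dropout = 0.2)
  n1 <- generate_street_network(cfg)
  n2 <- generate_street_network(cfg)
  expect_identical(n1$edges, n2$edges)
  expect_gte(n1$main_component_frac, 0.9)
})

test_that("excessive dropout that disconnects the grid is rejected", {
  cfg <- lattice_city_config(seed = 1L)
  cfg$edge_dropout_frac <- 0.49 # bypasses constructor, still < 0.5
  expect_error(generate_street_network(cfg), "disconnect")
})

test_that("the density gradient respects floor, peak and symmetry", {
  cfg <- lattice_city_config()
  cfg$anisotropy_ratio <- 1
  r <- generate_density_raster(cfg)
  expect_true(all(r$values >= cfg$density_floor_residents_km2))
  expect_lt(abs(max(r$values) - cfg$density_peak_residents_km2) /
    cfg$density_peak_residents_km2, 0.05)
  # radial symmetry: equidistant points from the peak agree to < 1%
  d1 <- raster_at(r, 500 + 200, 500)
  d2 <- raster_at(r, 500, 500 + 200)
  expect_lt(abs(d1 - d2) / d1, 0.01)
  # degenerate gradient: flat raster
  cfg$density_floor_residents_km2 <- cfg$density_peak_residents_km2
  flat <- generate_density_raster(cfg)
  expect_equal(diff(range(flat$values)), 0)
})

test_that("raster integration reproduces the reported resident total", {
  r <- generate_density_raster(lattice_city_config())
  # independent summation oracle over tidy cells
  cells <- tidy(r)
  oracle <- sum(cells$value) * (r$cell_size_m / 1000)^2
  expect_lt(abs(raster_total_residents(r) - oracle) / oracle, 0.001)
  expect_equal(attr(r, "total_residents"), raster_total_residents(r))
})

test_that("intersections are exactly the degree >= 3 nodes", {
  cfg <- lattice_city_config()
  net <- generate_street_network(cfg)
  dens <- generate_density_raster(cfg)
  lay <- generate_point_layer("intersections", dens, net, cfg)
  # 11 x 11 lattice: all but the 4 corner nodes have degree >= 3
  expect_equal(npoints(lay), 117)
  expect_setequal(
    paste(lay$x, lay$y),
    paste(net$nodes$x[net$nodes$degree >= 3], net$nodes$y[net$nodes$degree >= 3])
  )
})

test_that("sampled layer counts match the Poisson expectation", {
  cfg <- lattice_city_config()
  cfg$density_floor_residents_km2 <- 2000
  cfg$density_peak_residents_km2 <- 2000
  cfg$points_per_1000_residents <- c(transit = 30, open_space = 0)
  net <- generate_street_network(cfg)
  dens <- generate_density_raster(cfg)
  expected <- 30 * raster_total_residents(dens) / 1000
  counts <- vapply(1:200, function(s) {
    cfg_s <- cfg
    cfg_s$seed <- 1000L + s
    npoints(generate_point_layer("transit", dens, net, cfg_s))
  }, numeric(1))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se)
  # zero rate -> empty pattern
  lay0 <- generate_point_layer("open_space", dens, net, cfg)
  expect_equal(npoints(lay0), 0)
})

test_that("cohort marginals and outcome match the generative model", {
  dens <- small_city()$dens
  # intercept-only outcome: all betas zero except intercept log(60)
  tb <- default_true_beta()
  for (g in names(tb)) {
    tb[[g]][] <- 0
    tb[[g]]["intercept"] <- log(60)
  }
  co <- school_cohort(2000, seed = 31L, true_beta = tb)
  se <- sd(co$mvpa_min_per_day) / sqrt(nrow(co))
  expect_lt(abs(mean(co$mvpa_min_per_day) - 60), 3 * se)
  # school-age split: expected 300 of 400 at the default fraction
  cc <- cohort_config(n_children = 400, seed = 5L)
  expect_equal(cc$frac_school_age * cc$n_children, 300)
  counts <- vapply(1:100, function(s) {
    cc_s <- cohort_config(n_children = 400, seed = 7000L + s)
    sum(generate_cohort(cc_s, dens)$cohort$age_group == "school")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 300), 3 * sd(counts) / sqrt(100))
})

test_that("cohort generation is byte-identical on rerun", {
  dens <- small_city()$dens
  cc <- cohort_config(n_children = 50, seed = 9L)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_table_csv(generate_cohort(cc, dens)$cohort, f1)
  write_table_csv(generate_cohort(cc, dens)$cohort, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("truth object recomputes every linear predictor exactly", {
  dens <- small_city()$dens
  cc <- cohort_config(n_children = 80, seed = 13L)
  gen <- generate_cohort(cc, dens,
    truth_exposure_fn = function(x, y) raster_at(dens, x, y) / 1000)
  eta <- kernelhoods:::recompute_linear_predictor(gen$cohort, cc)
  expect_equal(eta, gen$truth$linear_predictor, tolerance = 1e-12)
})

test_that("epoch series honour wear windows, bouts and the exact round trip", {
  ep <- generate_epoch_counts("c1", 60, n_days = 4,
    start_date = as.Date("2007-10-05"), # a Friday
    config = epoch_config(noise = "none"))
  expect_equal(unique(diff(as.numeric(ep$timestamp[ep$date == ep$date[1]]))), 15)
  hab <- process_epochs(ep)
  expect_equal(hab$mvpa_min_per_day, 60)
  expect_true(hab$included)
  # two days only -> fails the three-consecutive-days rule downstream
  ep2 <- generate_epoch_counts("c2", 45, n_days = 2,
    start_date = as.Date("2007-10-06"))
  expect_false(process_epochs(ep2)$included)
  # habitual MVPA larger than the wear window is rejected
  expect_error(
    generate_epoch_counts("c3", 15 * 60, config = epoch_config(
      wear_start_hour = 8, wear_end_hour = 20)),
    "wear window")
})

test_that("residential density and open-space exposure are positively coupled", {
  city <- small_city()
  surf <- suppressWarnings(
    kernel_intensity_surface(city$layers$open_space, bw_fixed(500)))
  cc <- cohort_config(n_children = 250, seed = 17L)
  co <- generate_cohort(cc, city$dens,
    truth_exposure_fn = function(x, y) surface_at(surf, x, y))$cohort
  rho <- cor(raster_at(city$dens, co$home_x, co$home_y), co$true_exposure,
    method = "spearman")
  expect_gt(rho, 0)
})
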