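# simple intensity, kernel sums, edge correction, surfaces

test_that("simple intensity is count over area with boundary points included", {
  w <- window_rect(1000, 500) # 0.5 km^2
  p <- point_pattern(c(100, 200, 300), c(100, 200, 300), w)
  expect_equal(simple_intensity(p, w), 6)
  expect_equal(simple_intensity(point_pattern(numeric(0), numeric(0), w), w), 0)
  # boundary point counts
  pb <- point_pattern(c(0, 500), c(0, 250), w)
  expect_equal(simple_intensity(pb, w), 4)
  # identity case: full window equals n / |W|
  pr <- uniform_pattern(37, seed = 3)
  expect_equal(simple_intensity(pr, pr$window), 37 / window_area_km2(pr$window))
  expect_error(simple_intensity(p, window_rect(1e-9, 1e-9)), NA) # tiny but positive is fine
})

test_that("kernel density matches closed forms at a point", {
  w <- window_rect(1000, 1000)
  p1 <- point_pattern(500, 500, w)
  s <- 100
  expect_equal(gaussian_kernel_density(500, 500, p1, bw_iso(s)),
    1 / (2 * pi * s^2), tolerance = 1e-12)
  # far tail is negligible
  expect_lt(gaussian_kernel_density(500 + 7 * s, 500, p1, bw_iso(s)),
    1e-6 / (2 * pi * s^2))
  # coincident points double the contribution (linearity)
  p2 <- point_pattern(c(500, 500), c(500, 500), w)
  expect_equal(gaussian_kernel_density(500, 500, p2, bw_iso(s)),
    2 / (2 * pi * s^2), tolerance = 1e-12)
})

test_that("edge correction hits the analytic interior/edge/corner weights", {
  w <- window_rect(2000, 2000)
  bw <- bw_iso(20) # window_width / 100
  expect_equal(edge_correction(1000, 1000, bw, w), 1)
  expect_equal(edge_correction(1000, 0, bw, w), 2, tolerance = 1e-3)
  expect_equal(edge_correction(0, 0, bw, w), 4, tolerance = 1e-3)
  # same analytic values under an anisotropic bandwidth
  S <- matrix(c(30^2, 0, 0, 15^2), 2)
  expect_equal(edge_correction(1000, 0, bw_aniso(S), w), 2, tolerance = 1e-3)
  expect_equal(edge_correction(0, 0, bw_aniso(S), w), 4, tolerance = 1e-3)
  # a bandwidth far larger than the window trips the mass floor
  expect_error(edge_correction(1000, 1000, bw_iso(1e6), w), "floor")
})

test_that("anisotropic rectangle masses agree with quadrature", {
  w <- window_rect(1200, 900)
  S <- matrix(c(150^2, 0.5 * 150 * 90, 0.5 * 150 * 90, 90^2), 2)
  pts <- cbind(x = c(600, 100, 50, 1150), y = c(450, 80, 850, 40))
  for (i in seq_len(nrow(pts))) {
    m <- kernelhoods:::kernel_window_mass(pts[i, 1], pts[i, 2], bw_aniso(S), w)
    # midpoint quadrature oracle on a fine grid
    h <- 5
    gx <- seq(h / 2, 1200, by = h)
    gy <- seq(h / 2, 900, by = h)
    cx <- rep(gx, times = length(gy))
    cy <- rep(gy, each = length(gx))
    oracle <- sum(brute_kernel_sum(cx, cy, pts[i, 1], pts[i, 2], S)) * h^2
    expect_equal(unname(m), oracle, tolerance = 1e-4)
  }
})

test_that("surface cells equal an independently coded brute-force kernel sum", {
  p <- uniform_pattern(25, seed = 11, w = 1500)
  for (bw in list(bw_iso(200), bw_aniso(matrix(c(250^2, 0.4 * 250 * 120,
    0.4 * 250 * 120, 120^2), 2)))) {
    surf <- suppressWarnings(
      kernel_intensity_surface(p, bw, cell_size_m = 125, edge_corrected = FALSE))
    gx <- surf$x0 + (seq_len(surf$nx) - 0.5) * surf$cell_size_m
    gy <- surf$y0 + (seq_len(surf$ny) - 0.5) * surf$cell_size_m
    probe <- expand.grid(ix = c(1, 5, 12), iy = c(2, 7, 11))
    for (k in seq_len(nrow(probe))) {
      got <- surf$values[probe$iy[k], probe$ix[k]]
      want <- brute_kernel_sum(gx[probe$ix[k]], gy[probe$iy[k]],
        p$x, p$y, bw_cov(bw)) * 1e6
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("edge-corrected surfaces conserve mass and raw surfaces integrate below n", {
  for (seed in 1:3) {
    p <- uniform_pattern(40, seed = 100 + seed)
    surf <- kernel_intensity_surface(p, bw_iso(250))
    expect_lt(abs(surface_integral(surf) - 40) / 40, 0.02)
    raw <- kernel_intensity_surface(p, bw_iso(250), edge_corrected = FALSE)
    expect_lt(surface_integral(raw), surface_integral(surf))
    # the location-indexed variant conserves mass only approximately
    uni <- kernel_intensity_surface(p, bw_iso(250), correction = "uniform")
    expect_gte(abs(surface_integral(uni) - 40),
      abs(surface_integral(surf) - 40) - 1e-6)
  }
  # empty pattern: all-zero surface
  w <- window_rect(2000, 2000)
  s0 <- kernel_intensity_surface(point_pattern(numeric(0), numeric(0), w),
    bw_iso(250))
  expect_true(all(s0$values == 0))
})

test_that("interior cells of a homogeneous pattern recover the true intensity", {
  # lambda = 50 / km^2 on a 6x6 km window; the location-indexed correction
  # is pointwise unbiased for a homogeneous process (E[w(s) sum K] =
  # lambda), so interior cells recover the truth; the mass-conserving
  # per-point form trades this for exact integration (see the vignette)
  means <- vapply(1:100, function(s) {
    p <- with_test_seed(400 + s, {
      n <- rpois(1, 50 * 36)
      point_pattern(runif(n, 0, 6000), runif(n, 0, 6000),
        window_rect(6000, 6000))
    })
    surf <- kernel_intensity_surface(p, bw_iso(500), cell_size_m = 200,
      correction = "uniform")
    gx <- surf$x0 + (seq_len(surf$nx) - 0.5) * surf$cell_size_m
    gy <- surf$y0 + (seq_len(surf$ny) - 0.5) * surf$cell_size_m
    interior <- outer(gy > 1250 & gy < 4750, gx > 1250 & gx < 4750, "&")
    mean(surf$values[interior])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 50), 3 * se)
})

test_that("smoothing is monotone: cell-wise variance falls as sigma grows", {
  p <- uniform_pattern(60, seed = 21)
  sigmas <- c(100, 200, 400, 800)
  vars <- vapply(sigmas, function(s) {
    var(as.vector(kernel_intensity_surface(p, bw_iso(s),
      cell_size_m = 50)$values))
  }, numeric(1))
  expect_true(all(diff(vars) <= 0))
})

test_that("simple intensity matches the surface integral over the window", {
  p <- uniform_pattern(45, seed = 33)
  surf <- kernel_intensity_surface(p, bw_iso(300))
  lhs <- simple_intensity(p, p$window)
  rhs <- surface_integral(surf) / window_area_km2(p$window)
  expect_lt(abs(lhs - rhs) / lhs, 0.02)
})
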