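# bandwidth constructors, cross-validated selection, adaptive scaling

test_that("fixed bandwidth constructor validates and defaults to 500 m", {
  b <- bw_fixed()
  expect_equal(b$sigma_m, 500)
  expect_equal(b$form, "isotropic")
  expect_equal(bw_fixed(250)$sigma_m, 250)
  expect_error(bw_fixed(0), "positive")
  expect_error(bw_aniso(matrix(c(1, 2, 2, 1), 2)), "positive definite")
  expect_error(bw_aniso(matrix(c(1, 2, 3, 4), 2)), "symmetric")
})

test_that("MSE-CV arg-min matches an independent brute-force grid evaluation", {
  p <- uniform_pattern(40, seed = 5)
  res <- bw_mse_cv(p)
  expect_true(res$converged)
  # oracle: direct numeric evaluation of the criterion at every grid sigma,
  # from scratch (double loop over distinct pairs)
  d <- as.matrix(dist(cbind(p$x, p$y)))
  n <- npoints(p)
  oracle <- vapply(res$criterion$sigma, function(s) {
    tot_int <- 0
    tot_loo <- 0
    for (i in 1:n) {
      for (j in 1:n) {
        tot_int <- tot_int +
          exp(-d[i, j]^2 / (4 * s^2)) / (2 * pi * 2 * s^2)
        if (i != j) {
          tot_loo <- tot_loo + exp(-d[i, j]^2 / (2 * s^2)) / (2 * pi * s^2)
        }
      }
    }
    tot_int - 2 * tot_loo
  }, numeric(1))
  expect_equal(res$criterion$value, oracle, tolerance = 1e-10)
  expect_equal(res$bandwidth$sigma_m,
    res$criterion$sigma[which.min(oracle)])
})

test_that("MSE-CV prefers smaller bandwidths for tight clusters", {
  wins <- vapply(1:20, function(s) {
    cl <- with_test_seed(500 + s, {
      w <- window_rect(2000, 2000)
      point_pattern(pmin(2000, pmax(0, rnorm(50, 1000, 30))),
        pmin(2000, pmax(0, rnorm(50, 1000, 30))), w)
    })
    un <- uniform_pattern(50, seed = 700 + s)
    bw_mse_cv(cl)$bandwidth$sigma_m < bw_mse_cv(un)$bandwidth$sigma_m
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("exact duplicates collapse the MSE-CV criterion toward zero bandwidth", {
  # the known duplicates pathology of cross-validated bandwidths: with
  # every point doubled the leave-one-out term diverges as sigma -> 0, so
  # the criterion is minimised at the grid lower end; the trace reflects it
  p <- uniform_pattern(30, seed = 9)
  p2 <- point_pattern(rep(p$x, 2), rep(p$y, 2), p$window)
  r1 <- bw_mse_cv(p)
  r2 <- bw_mse_cv(p2)
  expect_gt(r1$bandwidth$sigma_m, min(r1$criterion$sigma))
  expect_equal(r2$bandwidth$sigma_m, min(r2$criterion$sigma))
  expect_lt(min(r2$criterion$value), min(r1$criterion$value))
})

test_that("MSE-CV guards: too few points and flat criteria", {
  w <- window_rect(1000, 1000)
  small <- point_pattern(runif(5, 0, 1000), runif(5, 0, 1000), w)
  expect_error(bw_mse_cv(small), "at least 10")
  expect_error(bw_mse_cv(uniform_pattern(20, seed = 2), n_sigma = 10),
    "at least 20 candidate")
})

test_that("LSCV objective matches numeric quadrature on a fine grid", {
  p <- uniform_pattern(25, seed = 13, w = 1500)
  for (S in list(diag(2) * 180^2,
    matrix(c(220^2, 0.4 * 220 * 130, 0.4 * 220 * 130, 130^2), 2))) {
    got <- lscv_objective(p, S)
    # quadrature oracle over an extended grid capturing the kernel mass
    h <- 20
    gx <- seq(-1500, 3000, by = h)
    gy <- seq(-1500, 3000, by = h)
    cx <- rep(gx, times = length(gy))
    cy <- rep(gy, each = length(gx))
    n <- npoints(p)
    fhat <- kernelhoods:::kernel_sum(cx, cy, p$x, p$y, S) / n
    int_f2 <- sum(fhat^2) * h^2
    loo <- vapply(seq_len(n), function(i) {
      sum(kernelhoods:::kernel_sum(p$x[i], p$y[i], p$x[-i], p$y[-i], S)) / (n - 1)
    }, numeric(1))
    oracle <- int_f2 - 2 * mean(loo)
    expect_equal(got, oracle, tolerance = 1e-6)
  }
})

test_that("LSCV selection is reproducible and reports its trace", {
  p <- uniform_pattern(60, seed = 17)
  r1 <- bw_lscv_aniso(p)
  r2 <- bw_lscv_aniso(p)
  expect_true(r1$converged)
  expect_equal(r1$bandwidth$Sigma, r2$bandwidth$Sigma)
  expect_gte(nrow(r1$criterion), 5)
  # the kept optimum realises the best recorded (possibly floor-penalised)
  # objective, which never undercuts the raw LSCV value there
  expect_lte(lscv_objective(p, r1$bandwidth$Sigma),
    min(r1$criterion$objective[r1$criterion$convergence == 0]) + 1e-12)
})

test_that("both selectors are translation invariant and scale equivariant", {
  p <- uniform_pattern(40, seed = 23)
  grid <- exp(seq(log(25), log(700), length.out = 24))
  base <- bw_mse_cv(p, sigma_grid = grid)$bandwidth$sigma_m
  # translation
  w2 <- window_rect(2000, 2000, origin = c(3000, 5000))
  pt <- point_pattern(p$x + 3000, p$y + 5000, w2)
  expect_equal(bw_mse_cv(pt, sigma_grid = grid)$bandwidth$sigma_m, base)
  expect_equal(bw_lscv_aniso(pt)$bandwidth$Sigma,
    bw_lscv_aniso(p)$bandwidth$Sigma, tolerance = 1e-4)
  # uniform rescaling: sigma scales linearly, Sigma quadratically
  c_scale <- 2.5
  ws <- window_rect(2000 * c_scale, 2000 * c_scale)
  ps <- point_pattern(p$x * c_scale, p$y * c_scale, ws)
  expect_equal(bw_mse_cv(ps, sigma_grid = grid * c_scale)$bandwidth$sigma_m,
    base * c_scale, tolerance = 1e-10)
  expect_equal(bw_lscv_aniso(ps)$bandwidth$Sigma,
    c_scale^2 * bw_lscv_aniso(p)$bandwidth$Sigma, tolerance = 1e-3)
})

test_that("adaptive scaling pivots at the pilot density and floors R_A", {
  expect_equal(adaptive_scale(bw_fixed(500), 2000)$sigma_m, 500)
  expect_equal(adaptive_scale(bw_fixed(500), 4000)$sigma_m, 250)
  expect_equal(adaptive_scale(bw_fixed(500), 1000)$sigma_m, 1000)
  expect_error(adaptive_scale(bw_fixed(500), -5), "positive")
  # monotone decreasing in R_A
  sig <- vapply(c(500, 1000, 2000, 4000, 8000), function(r) {
    adaptive_scale(bw_fixed(500), r)$sigma_m
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
  # floor: below 100 residents/km^2 the factor stops growing
  expect_equal(adaptive_scale(bw_fixed(500), 10)$sigma_m,
    adaptive_scale(bw_fixed(500), 100)$sigma_m)
  expect_true(adaptive_scale(bw_fixed(500), 10)$floored)
  # anisotropic: linear spread scales by the same factor
  S <- matrix(c(300^2, 0, 0, 150^2), 2)
  sc <- adaptive_scale(bw_aniso(S), 4000)
  expect_equal(sc$Sigma, S / 4, tolerance = 1e-12)
  expect_equal(sc$parent, "lscv")
  expect_equal(sc$factor, 0.5)
})
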