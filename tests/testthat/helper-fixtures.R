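# shared small fixtures, built in code; memoised per test session

# full 11 x 11 lattice in a 1 km^2 window
lattice_city_config <- function(seed = 1L, dropout = 0) {
  city_config(
    window_width_m = 1000, window_height_m = 1000, grid_spacing_m = 100,
    edge_dropout_frac = dropout,
    density_peak_residents_km2 = 4000, density_floor_residents_km2 = 200,
    density_cell_m = 50, seed = seed
  )
}

# compact town used for exposure-level tests (kept small for speed)
small_city <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- city_config(
        window_width_m = 3000, window_height_m = 3000, grid_spacing_m = 150,
        density_peak_residents_km2 = 4000, density_floor_residents_km2 = 200,
        seed = 42L
      )
      net <- generate_street_network(cfg)
      dens <- generate_density_raster(cfg)
      layers <- list(
        intersections = generate_point_layer("intersections", dens, net, cfg),
        transit = generate_point_layer("transit", dens, net, cfg),
        open_space = generate_point_layer("open_space", dens, net, cfg)
      )
      cache <<- list(cfg = cfg, net = net, dens = dens, layers = layers)
    }
    cache
  }
})

# a single straight edge embedded in a large window (closed-form geometry)
line_network <- function(width = 4000, x1 = 500, x2 = 3500, y = 2000) {
  street_network(
    data.frame(id = 1:2, x = c(x1, x2), y = c(y, y)),
    data.frame(from = 1, to = 2),
    window_rect(width, width)
  )
}

# uniform pattern in a rectangle window, seeded
uniform_pattern <- function(n, seed, w = 2000, kind = "points") {
  win <- window_rect(w, w)
  with_test_seed(seed, point_pattern(runif(n, 0, w), runif(n, 0, w), win, kind))
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# independent brute-force Gaussian kernel sum (oracle; scalar loops only)
brute_kernel_sum <- function(ex, ey, px, py, Sigma) {
  Sinv <- solve(Sigma)
  cst <- 1 / (2 * pi * sqrt(det(Sigma)))
  out <- numeric(length(ex))
  for (i in seq_along(ex)) {
    acc <- 0
    for (j in seq_along(px)) {
      d <- c(ex[i] - px[j], ey[i] - py[j])
      acc <- acc + exp(-0.5 * sum(d * (Sinv %*% d)))
    }
    out[i] <- cst * acc
  }
  out
}

# independent oracle: direct maximization of the full gamma log-likelihood
# over (beta, log nu) with analytic gradient, started from a log-scale
# least-squares fit
direct_ml_oracle <- function(data, formula) {
  X <- stats::model.matrix(formula, data)
  y <- stats::model.response(stats::model.frame(formula, data))
  nll <- function(th) {
    beta <- th[-length(th)]
    nu <- exp(th[length(th)])
    mu <- as.vector(exp(X %*% beta))
    -sum(stats::dgamma(y, shape = nu, rate = nu / mu, log = TRUE))
  }
  gr <- function(th) {
    beta <- th[-length(th)]
    nu <- exp(th[length(th)])
    mu <- as.vector(exp(X %*% beta))
    c(-as.vector(t(X) %*% (nu * (y / mu - 1))),
      -nu * sum(log(nu) + 1 - digamma(nu) + log(y) - log(mu) - y / mu))
  }
  o <- suppressWarnings(stats::optim(c(qr.solve(X, log(y)), 0), nll, gr,
    method = "BFGS", control = list(maxit = 5000, reltol = 1e-15)))
  list(beta = o$par[seq_len(ncol(X))], shape = exp(o$par[ncol(X) + 1]),
    logLik = -o$value)
}

# school-only cohort draw used by several model tests
school_cohort <- function(n, seed, true_beta = NULL, dens = NULL) {
  if (is.null(dens)) dens <- small_city()$dens
  cc <- cohort_config(n_children = n, frac_school_age = 1, seed = seed)
  if (!is.null(true_beta)) cc$true_beta <- true_beta
  suppressWarnings(generate_cohort(cc, dens)$cohort)
}
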