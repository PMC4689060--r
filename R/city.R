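#' Synthetic city configuration
#'
#' Parameters of the seeded synthetic study region: a rectangular window with
#' a gridded street network (a fraction of edges dropped for irregularity)
#' and an elliptical residential-density gradient. Defaults emulate a
#' mid-sized German town: a 7.9 x 7.9 km window (62.4 km^2) whose density
#' gradient integrates to about 77,000 residents, with block spacing of
#' ~130 m giving an intersection density near 60/km^2. Neighborhood
#' distances up to 2 km then stay small relative to the region, as in a
#' real town. Tests and demos pass smaller explicit extents.
#'
#' @param window_width_m,window_height_m window extents in metres.
#' @param grid_spacing_m street block size in metres.
#' @param edge_dropout_frac fraction of grid edges removed (in `[0, 0.5)`).
#' @param density_peak_residents_km2,density_floor_residents_km2 extremes of
#'   the elliptical density gradient.
#' @param anisotropy_ratio major/minor axis ratio of the density ellipse
#'   (>= 1).
#' @param points_per_1000_residents named vector: expected points per 1000
#'   residents for the sampled layers (`transit`, `open_space`).
#' @param layer_clustering named vector of Neyman-Scott cluster dispersions
#'   (>= 0; 0 = plain inhomogeneous Poisson).
#' @param density_cell_m raster cell size for the density gradient.
#' @param seed integer root seed.
#' @return a `kh_city_config` list.
#' @export
city_config <- function(window_width_m = 7900,
                        window_height_m = 7900,
                        grid_spacing_m = 130,
                        edge_dropout_frac = 0.10,
                        density_peak_residents_km2 = 7250,
                        density_floor_residents_km2 = 200,
                        anisotropy_ratio = 1.5,
                        points_per_1000_residents = c(transit = 4, open_space = 3.2),
                        layer_clustering = c(transit = 0, open_space = 0),
                        density_cell_m = 50,
                        seed = 1L) {
  assert_scalar_pos(window_width_m, "window_width_m")
  assert_scalar_pos(window_height_m, "window_height_m")
  assert_scalar_pos(grid_spacing_m, "grid_spacing_m")
  assert_prob(edge_dropout_frac, "edge_dropout_frac")
  if (edge_dropout_frac >= 0.5) abort("edge_dropout_frac must be < 0.5")
  assert_scalar_pos(density_peak_residents_km2, "density_peak_residents_km2")
  if (density_floor_residents_km2 < 0 ||
    density_floor_residents_km2 > density_peak_residents_km2) {
    abort("need 0 <= density_floor <= density_peak")
  }
  if (anisotropy_ratio < 1) abort("anisotropy_ratio must be >= 1")
  if (any(points_per_1000_residents < 0)) {
    abort("points_per_1000_residents must be non-negative")
  }
  if (any(layer_clustering < 0)) abort("layer_clustering must be >= 0")
  structure(
    list(
      window_width_m = window_width_m, window_height_m = window_height_m,
      grid_spacing_m = grid_spacing_m, edge_dropout_frac = edge_dropout_frac,
      density_peak_residents_km2 = density_peak_residents_km2,
      density_floor_residents_km2 = density_floor_residents_km2,
      anisotropy_ratio = anisotropy_ratio,
      points_per_1000_residents = points_per_1000_residents,
      layer_clustering = layer_clustering,
      density_cell_m = density_cell_m,
      seed = as.integer(seed)
    ),
    class = "kh_city_config"
  )
}

#' Synthetic cohort configuration
#'
#' Marginals of the simulated child cohort and the generative outcome model.
#' Default marginals follow the descriptive structure of a 2-9.9-year-old
#' accelerometer cohort: 75% school-age (6-9.9 y) children, 51.5% girls,
#' parental-education (ISCED) shares and safety-concern rates specified per
#' age group/sex stratum, and 29-30% of measurements in spring/summer.
#' Habitual MVPA (min/day) is drawn from a gamma distribution with log-link
#' mean `exp(X beta)` using `true_beta`; the default coefficients are the
#' age-group-specific multiplicative effects of the basic individual-level
#' model (e.g. season 1.17 and safety 0.99 in school children, age 1.28 and
#' safety 0.86 in pre-school children), with intercepts calibrated so mean
#' MVPA is ~62 (school) and ~56 (pre-school) min/day.
#'
#' @param n_children cohort size (>= 1).
#' @param frac_school_age probability of the school age group.
#' @param frac_girls probability of sex "girl".
#' @param isced_probs list with elements `school`, `preschool`, each a named
#'   probability vector over `low`, `medium`, `high` (summing to 1).
#' @param safety_probs named vector of safety-concern probabilities for the
#'   four age-by-sex strata.
#' @param season_spring_summer_prob probability of a spring/summer
#'   measurement.
#' @param true_beta list with elements `school`, `preschool`: named log-scale
#'   coefficient vectors over `intercept`, `age`, `bmi_z`, `weartime`,
#'   `season_spring_summer`, `safety_yes`, `isced_low`, `isced_high`,
#'   `exposure`.
#' @param gamma_shape gamma shape parameter `nu` of the MVPA distribution.
#' @param weartime_mean_h,weartime_sd_h wear-time distribution (truncated
#'   normal on `[8, 16]` hours).
#' @param seed integer root seed.
#' @return a `kh_cohort_config` list.
#' @export
cohort_config <- function(n_children = 400,
                          frac_school_age = 0.75,
                          frac_girls = 0.515,
                          isced_probs = list(
                            school = c(low = 0.23, medium = 0.56, high = 0.21),
                            preschool = c(low = 0.13, medium = 0.72, high = 0.15)
                          ),
                          safety_probs = c(
                            school_boys = 0.365, school_girls = 0.344,
                            preschool_boys = 0.386, preschool_girls = 0.581
                          ),
                          season_spring_summer_prob = 0.29,
                          true_beta = default_true_beta(),
                          gamma_shape = 8,
                          weartime_mean_h = 11.5,
                          weartime_sd_h = 1.3,
                          seed = 1L) {
  if (n_children < 1) abort("n_children must be >= 1")
  assert_prob(frac_school_age, "frac_school_age")
  assert_prob(frac_girls, "frac_girls")
  for (g in c("school", "preschool")) {
    p <- isced_probs[[g]]
    assert_prob(p, paste0("isced_probs$", g))
    if (abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("isced_probs$%s must sum to 1", g))
    }
  }
  assert_prob(safety_probs, "safety_probs")
  assert_prob(season_spring_summer_prob, "season_spring_summer_prob")
  assert_scalar_pos(gamma_shape, "gamma_shape")
  structure(
    list(
      n_children = as.integer(n_children),
      frac_school_age = frac_school_age, frac_girls = frac_girls,
      isced_probs = isced_probs, safety_probs = safety_probs,
      season_spring_summer_prob = season_spring_summer_prob,
      true_beta = true_beta, gamma_shape = gamma_shape,
      weartime_mean_h = weartime_mean_h, weartime_sd_h = weartime_sd_h,
      seed = as.integer(seed)
    ),
    class = "kh_cohort_config"
  )
}

#' @rdname cohort_config
#' @export
default_true_beta <- function() {
  list(
    school = c(
      intercept = 3.888, age = log(0.97), bmi_z = log(0.95),
      weartime = log(1.04), season_spring_summer = log(1.17),
      safety_yes = log(0.99), isced_low = log(0.95), isced_high = log(1.01),
      exposure = 0
    ),
    preschool = c(
      intercept = 3.026, age = log(1.28), bmi_z = log(1.03),
      weartime = 0, season_spring_summer = log(0.99),
      safety_yes = log(0.86), isced_low = log(1.12), isced_high = log(1.12),
      exposure = 0
    )
  )
}
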