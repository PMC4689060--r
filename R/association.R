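# ---- stratified basic and exposure models, pattern tables ---------------

# fixed reference levels: medium ISCED, no safety concerns, autumn/winter
prepare_model_data <- function(cohort) {
  cohort <- cohort[cohort$mvpa_min_per_day > 0 | is.na(cohort$mvpa_min_per_day), , drop = FALSE]
  cohort$isced <- factor(cohort$isced, levels = c("medium", "low", "high"))
  cohort$safety_concerns <- factor(cohort$safety_concerns, levels = c("no", "yes"))
  cohort$season <- factor(cohort$season, levels = c("autumn_winter", "spring_summer"))
  cohort
}

basic_formula <- function(extra = NULL) {
  rhs <- "age_years + bmi_z + valid_weartime_h + season + safety_concerns + isced"
  if (!is.null(extra)) rhs <- paste(rhs, "+", extra)
  as.formula(paste("mvpa_min_per_day ~", rhs))
}

default_strata <- function() {
  tibble(
    stratum = c("school_all", "school_boys", "school_girls",
      "preschool_all", "preschool_boys", "preschool_girls"),
    age_group = rep(c("school", "preschool"), each = 3),
    sex = rep(c(NA, "boy", "girl"), times = 2)
  )
}

stratum_rows <- function(cohort, age_group, sex) {
  sel <- cohort$age_group == age_group
  if (!is.na(sex)) sel <- sel & cohort$sex == sex
  cohort[sel, , drop = FALSE]
}

#' Fit the basic individual-level models by stratum
#'
#' Fits the gamma log-link model of habitual MVPA on the basic covariate set
#' (age, BMI z-score, valid wear time, season, parental safety concerns,
#' ISCED dummies with medium as reference) in the six strata: all/boys/girls
#' within school-age and pre-school children. Sex is never a covariate
#' inside sex strata. Children with non-positive MVPA (possible in synthetic
#' nulls, outside the gamma support) are excluded with a message.
#'
#' @param cohort child-record tibble (see [generate_cohort()]).
#' @param strata optional tibble with columns `stratum`, `age_group`, `sex`
#'   (NA sex = both); defaults to the six study strata.
#' @return named list of `kh_gamma_fit` objects, with attribute `report`
#'   holding a long table of per-term `exp_estimate`, `p.value` and AIC per
#'   stratum.
#' @export
fit_basic_models <- function(cohort, strata = default_strata()) {
  n0 <- nrow(cohort)
  cohort <- prepare_model_data(cohort)
  if (nrow(cohort) < n0) {
    inform(sprintf("excluded %d children with non-positive MVPA (gamma support)",
      n0 - nrow(cohort)))
  }
  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    dat <- stratum_rows(cohort, strata$age_group[i], strata$sex[i])
    f <- tryCatch(fit_gamma_log(dat, basic_formula()),
      error = function(e) {
        warn(sprintf("basic model failed in stratum '%s': %s",
          strata$stratum[i], conditionMessage(e)))
        NULL
      })
    if (is.null(f)) next
    fits[[strata$stratum[i]]] <- f
    rows[[i]] <- tidy.kh_gamma_fit(f) |>
      mutate(stratum = strata$stratum[i], n = f$n, aic = f$aic)
  }
  attr(fits, "report") <- bind_rows(rows)
  fits
}

#' Pattern analysis: exposure effects by measure and distance
#'
#' For each stratum, each exposure layer kind, each intensity measure and
#' each network distance, refits the basic model with the exposure column
#' added as one extra term, and collects the exposure effect `exp(beta)`,
#' its p-value, and the model AIC into a pattern table (the measure-by-
#' distance grid of effect/p/goodness-of-fit patterns). Non-converged cells
#' are kept as rows with `converged = FALSE`, never silently dropped. No
#' multiple-testing adjustment is applied across the grid: raw p-values are
#' reported.
#'
#' @param cohort child-record tibble with `mvpa_min_per_day`.
#' @param exposures exposure record tibble from [build_exposure_matrix()]
#'   (columns `child_id`, `kind`, `measure`, `distance_m`, `value`).
#' @param strata as in [fit_basic_models()]; defaults to school-age strata
#'   plus pre-school strata.
#' @return a tibble of class `kh_pattern_table` with one row per
#'   (stratum, kind, measure, distance): `exp_beta`, `p_value`, `aic`, `n`,
#'   `converged`.
#' @export
run_pattern_analysis <- function(cohort, exposures, strata = default_strata()) {
  cohort <- prepare_model_data(cohort)
  grid <- exposures |>
    dplyr::distinct(.data$kind, .data$measure, .data$distance_m)
  out <- vector("list", nrow(strata) * nrow(grid))
  ptr <- 0L
  for (i in seq_len(nrow(strata))) {
    dat_s <- stratum_rows(cohort, strata$age_group[i], strata$sex[i])
    for (j in seq_len(nrow(grid))) {
      exp_j <- exposures |>
        filter(.data$kind == grid$kind[j],
          .data$measure == grid$measure[j],
          .data$distance_m == grid$distance_m[j]) |>
        select("child_id", exposure = "value")
      dat <- dplyr::inner_join(dat_s, exp_j, by = "child_id")
      ptr <- ptr + 1L
      row <- tibble(
        stratum = strata$stratum[i], kind = grid$kind[j],
        measure = grid$measure[j], distance_m = grid$distance_m[j],
        exp_beta = NA_real_, p_value = NA_real_, aic = NA_real_,
        n = nrow(dat), converged = FALSE
      )
      fit <- tryCatch(
        suppressWarnings(fit_gamma_log(dat, basic_formula("exposure"))),
        error = function(e) NULL
      )
      if (!is.null(fit) && fit$converged) {
        co <- fit$coef[fit$coef$term == "exposure", ]
        row$exp_beta <- co$exp_estimate
        row$p_value <- co$p.value
        row$aic <- fit$aic
        row$converged <- TRUE
      }
      out[[ptr]] <- row
    }
  }
  structure(bind_rows(out), class = c("kh_pattern_table", "tbl_df", "tbl", "data.frame"))
}

#' @export
autoplot.kh_pattern_table <- function(object, stratum = NULL, kind = NULL, ...) {
  df <- object
  if (!is.null(stratum)) df <- df[df$stratum %in% stratum, ]
  if (!is.null(kind)) df <- df[df$kind %in% kind, ]
  long <- df |>
    tidyr::pivot_longer(c("exp_beta", "p_value", "aic"),
      names_to = "metric", values_to = "value") |>
    mutate(metric = factor(.data$metric, levels = c("exp_beta", "p_value", "aic"),
      labels = c("exp(beta)", "p value", "AIC")))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$distance_m, y = .data$value, colour = .data$measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$metric),
      cols = ggplot2::vars(.data$stratum, .data$kind), scales = "free_y") +
    ggplot2::labs(x = "network distance [m]", y = NULL, colour = "measure")
}

#' Descriptive statistics by stratum
#'
#' Mean (SD) of the continuous variables and n (%) of the categorical
#' variables by the six age-by-sex strata; percentages are computed within
#' stratum.
#'
#' @param cohort child-record tibble.
#' @param strata as in [fit_basic_models()].
#' @return long tibble: `stratum`, `variable`, `level` (NA for continuous),
#'   `mean`, `sd`, `n`, `pct`.
#' @export
descriptive_table <- function(cohort, strata = default_strata()) {
  cont <- c("mvpa_min_per_day", "age_years", "bmi_z", "valid_weartime_h")
  cat_vars <- list(
    isced = c("low", "medium", "high"),
    safety_concerns = c("no", "yes"),
    season = c("autumn_winter", "spring_summer")
  )
  rows <- list()
  for (i in seq_len(nrow(strata))) {
    dat <- stratum_rows(cohort, strata$age_group[i], strata$sex[i])
    for (v in cont) {
      if (!v %in% names(dat)) next
      rows[[length(rows) + 1L]] <- tibble(
        stratum = strata$stratum[i], variable = v, level = NA_character_,
        mean = mean(dat[[v]]), sd = sd(dat[[v]]),
        n = nrow(dat), pct = NA_real_
      )
    }
    for (v in names(cat_vars)) {
      if (!v %in% names(dat)) next
      for (lv in cat_vars[[v]]) {
        nn <- sum(dat[[v]] == lv)
        rows[[length(rows) + 1L]] <- tibble(
          stratum = strata$stratum[i], variable = v, level = lv,
          mean = NA_real_, sd = NA_real_,
          n = nn, pct = 100 * nn / nrow(dat)
        )
      }
    }
  }
  bind_rows(rows)
}

#' Study sample accounting
#'
#' Applies the stated exclusions to a baseline accelerometer sample and the
#' configured cohort marginals: children living in the rural periphery and
#' children with missing questionnaire data are removed, the school-age
#' share follows `frac_school_age`, and the medium parental-education share
#' among school children follows the school ISCED probabilities.
#'
#' @param baseline_n baseline sample size with valid accelerometry.
#' @param excluded_rural children excluded as living outside the urban area.
#' @param excluded_missing children excluded for missing questionnaire data.
#' @param frac_school_age school-age fraction of the included sample.
#' @param isced_school named probability vector over low/medium/high for
#'   school children.
#' @return one-row tibble: `n_included`, `n_school`, `pct_school`,
#'   `pct_medium_isced_school`.
#' @export
sample_accounting <- function(baseline_n = 448, excluded_rural = 24,
                              excluded_missing = 24, frac_school_age = 0.75,
                              isced_school = c(low = 0.23, medium = 0.56, high = 0.21)) {
  n_inc <- baseline_n - excluded_rural - excluded_missing
  n_school <- round(n_inc * frac_school_age)
  tibble(
    n_included = n_inc,
    n_school = n_school,
    pct_school = 100 * n_school / n_inc,
    pct_medium_isced_school = 100 * round(isced_school[["medium"]] * n_school) / n_school
  )
}
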