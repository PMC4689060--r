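# ---- end-to-end pipeline -------------------------------------------------

#' Pipeline configuration
#'
#' Bundles the synthetic-city and cohort configurations with the exposure
#' settings, output directory and root seed for a full
#' simulate -> intensity -> exposure -> mvpa -> fit -> report run. The root
#' seed is fanned out to each stage through named streams, so changing one
#' stage's inputs leaves the other stages' draws untouched.
#'
#' @param out_dir output directory (created if missing).
#' @param city a [city_config()].
#' @param cohort a [cohort_config()].
#' @param exposure an [exposure_config()].
#' @param use_epochs simulate 15-s epoch series and derive the outcome
#'   through the accelerometry module (slower); otherwise the generative
#'   habitual MVPA is used directly.
#' @param epoch_days days of accelerometry per child when `use_epochs`.
#' @param exposure_effect optional named list `list(kind=, measure=,
#'   distance_m=, exp_beta=)`: plants a true exposure effect by generating
#'   the outcome from that measured exposure.
#' @param seed root seed; overrides the seeds inside `city` and `cohort`.
#' @return a `kh_pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            city = city_config(),
                            cohort = cohort_config(),
                            exposure = exposure_config(),
                            use_epochs = FALSE,
                            epoch_days = 7,
                            exposure_effect = NULL,
                            seed = 1L) {
  structure(
    list(out_dir = out_dir, city = city, cohort = cohort,
      exposure = exposure, use_epochs = use_epochs,
      epoch_days = epoch_days, exposure_effect = exposure_effect,
      seed = as.integer(seed)),
    class = "kh_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `out_dir`, `seed`, `use_epochs`, `epoch_days` and blocks
#' `city`, `cohort`, `exposure` whose entries override the corresponding
#' configuration defaults.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  city <- do.call(city_config, as_config_args(y$city, city_config))
  cohort <- do.call(cohort_config, as_config_args(y$cohort, cohort_config))
  exposure <- do.call(exposure_config, as_config_args(y$exposure, exposure_config))
  pipeline_config(
    out_dir = y$out_dir %||% "pipeline_out",
    city = city, cohort = cohort, exposure = exposure,
    use_epochs = isTRUE(y$use_epochs),
    epoch_days = y$epoch_days %||% 7,
    seed = y$seed %||% 1L
  )
}

as_config_args <- function(block, fn) {
  if (is.null(block)) return(list())
  keep <- intersect(names(block), names(formals(fn)))
  lapply(block[keep], function(v) if (is.list(v)) unlist(v) else v)
}

stage_files <- function(out_dir) {
  list(
    network = file.path(out_dir, "network.geojson"),
    density = file.path(out_dir, "density.asc"),
    layers = stats::setNames(
      file.path(out_dir, c("layer_intersections.geojson",
        "layer_transit.geojson", "layer_open_space.geojson")),
      c("intersections", "transit", "open_space")),
    cohort = file.path(out_dir, "cohort.csv"),
    truth = file.path(out_dir, "truth.json"),
    epochs = file.path(out_dir, "epochs.csv"),
    surfaces = file.path(out_dir, "surfaces"),
    exposures = file.path(out_dir, "exposures.csv"),
    exposure_summary = file.path(out_dir, "exposure_summary.csv"),
    mvpa = file.path(out_dir, "habitual_mvpa.csv"),
    basic_fit = file.path(out_dir, "basic_models.csv"),
    pattern = file.path(out_dir, "pattern_table.csv"),
    manifest = file.path(out_dir, "manifest.json")
  )
}

#' Validate pipeline input files
#'
#' Schema checks for the pipeline's file formats: cohort and epoch CSVs
#' (required columns, positive coordinates inside the declared window,
#' constant 15-s timestamp steps within child-days, non-negative counts),
#' GeoJSON point/line layers (geometry types, finite metric coordinates),
#' and ASCII rasters (header sanity, non-negative density). Violations are
#' returned, not raised.
#'
#' @param paths named list/vector of file paths; names select the check:
#'   `cohort`, `epochs`, `points`, `network`, `raster` (a name like
#'   `points2` also works).
#' @return tibble of violations (`file`, `id`, `rule`, `detail`); zero rows
#'   when everything is well-formed.
#' @export
validate_inputs <- function(paths) {
  out <- list()
  bad <- function(file, id, rule, detail) {
    out[[length(out) + 1L]] <<- tibble(file = file, id = as.character(id),
      rule = rule, detail = detail)
  }
  for (nm in names(paths)) {
    path <- paths[[nm]]
    kind <- sub("[0-9]*$", "", nm)
    if (!file.exists(path)) {
      bad(path, NA, "missing_file", "file does not exist")
      next
    }
    if (kind == "cohort") {
      x <- tryCatch(read_table_csv(path), error = function(e) NULL)
      need <- c("child_id", "home_x", "home_y", "age_years", "sex",
        "isced", "safety_concerns", "season")
      if (is.null(x)) {
        bad(path, NA, "unreadable", "could not parse CSV")
      } else {
        miss <- setdiff(need, names(x))
        if (length(miss)) {
          bad(path, NA, "missing_columns", paste(miss, collapse = ", "))
        }
        if (all(c("home_x", "home_y") %in% names(x))) {
          nf <- which(!is.finite(x$home_x) | !is.finite(x$home_y))
          for (i in nf) bad(path, x$child_id[i], "bad_coordinates", "non-finite home coordinate")
        }
      }
    } else if (kind == "epochs") {
      x <- tryCatch(read_table_csv(path), error = function(e) NULL)
      if (is.null(x) || !all(c("child_id", "timestamp", "counts") %in% names(x))) {
        bad(path, NA, "missing_columns", "need child_id, timestamp, counts")
      } else {
        if (any(x$counts < 0, na.rm = TRUE)) {
          bad(path, NA, "negative_counts", "counts must be >= 0")
        }
        x$date <- as.Date(x$timestamp)
        for (key in unique(paste(x$child_id, x$date))) {
          idx <- which(paste(x$child_id, x$date) == key)
          steps <- diff(as.numeric(x$timestamp[idx]))
          if (length(steps) && any(steps != 15)) {
            bad(path, key, "irregular_epochs",
              sprintf("timestamp steps of %s s (expected 15)",
                paste(unique(steps[steps != 15]), collapse = "/")))
          }
        }
      }
    } else if (kind == "points") {
      fc <- tryCatch(jsonlite::read_json(path), error = function(e) NULL)
      if (is.null(fc) || !identical(fc$type, "FeatureCollection")) {
        bad(path, NA, "not_feature_collection", "expected GeoJSON FeatureCollection")
      } else {
        for (i in seq_along(fc$features)) {
          g <- fc$features[[i]]$geometry
          if (!identical(g$type, "Point")) {
            bad(path, i, "wrong_geometry",
              sprintf("feature %d has geometry '%s', expected Point", i, g$type))
          } else if (any(!is.finite(as.numeric(unlist(g$coordinates))))) {
            bad(path, i, "bad_coordinates", "non-finite coordinate")
          }
        }
      }
    } else if (kind == "network") {
      fc <- tryCatch(jsonlite::read_json(path), error = function(e) NULL)
      if (is.null(fc) || !identical(fc$type, "FeatureCollection")) {
        bad(path, NA, "not_feature_collection", "expected GeoJSON FeatureCollection")
      } else {
        for (i in seq_along(fc$features)) {
          g <- fc$features[[i]]$geometry
          if (!identical(g$type, "LineString")) {
            bad(path, i, "wrong_geometry",
              sprintf("feature %d has geometry '%s', expected LineString", i, g$type))
          }
        }
      }
    } else if (kind == "raster") {
      r <- tryCatch(read_ascii_grid(path), error = function(e) NULL)
      if (is.null(r)) {
        bad(path, NA, "unreadable", "could not parse ASCII grid")
      } else if (any(r$values < 0, na.rm = TRUE)) {
        bad(path, NA, "negative_values", "density raster must be non-negative")
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(file = character(), id = character(),
      rule = character(), detail = character()))
  }
  bind_rows(out)
}

#' Run the full pipeline
#'
#' Executes simulate -> intensity -> exposure -> mvpa -> fit in order,
#' writing every intermediate product under `config$out_dir`, and returns a
#' run manifest with per-file checksums. With `resume = TRUE` a stage is
#' skipped (its products are re-loaded from disk) when the previous
#' manifest used the same configuration and seed, all its recorded output
#' files still match their checksums, and no upstream stage was re-run; a
#' recorded output whose checksum no longer matches makes that stage and
#' everything downstream fail with a named error, leaving upstream files
#' untouched. Any stage failure halts downstream stages, which are marked
#' `"stale"` in the manifest.
#'
#' @param config a [pipeline_config()].
#' @param resume skip up-to-date stages based on the previous manifest.
#' @param quiet suppress progress messages.
#' @return the manifest (list), invisibly; also written to
#'   `<out_dir>/manifest.json`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  stopifnot(inherits(config, "kh_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- stage_files(config$out_dir)
  say <- function(...) if (!quiet) inform(sprintf(...))
  config$city$seed <- stream_seed(config$seed, "city")
  config$cohort$seed <- stream_seed(config$seed, "cohort")
  config$exposure$seed <- stream_seed(config$seed, "exposure")
  n_warn <- 0L
  counting <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      n_warn <<- n_warn + 1L
      invokeRestart("muffleWarning")
    })
  }
  cfg_hash <- config_hash(config)
  prev <- if (resume && file.exists(files$manifest)) {
    tryCatch(jsonlite::read_json(files$manifest), error = function(e) NULL)
  }
  if (!is.null(prev) && !identical(prev$config_hash, cfg_hash)) prev <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("kernelhoods")),
    seed = config$seed,
    config_hash = cfg_hash,
    started = format(Sys.time(), tz = "UTC"),
    stages = list()
  )
  st <- new.env(parent = emptyenv()) # shared stage products
  st$config <- config
  stage_order <- c("simulate", "intensity", "exposure", "mvpa", "fit")
  bodies <- pipeline_stage_bodies()
  upstream_rerun <- FALSE
  finish <- function() {
    manifest$finished <- format(Sys.time(), tz = "UTC")
    manifest$warnings <- n_warn
    jsonlite::write_json(manifest, files$manifest, auto_unbox = TRUE,
      digits = NA)
    manifest
  }
  for (si in seq_along(stage_order)) {
    nm <- stage_order[si]
    prev_stage <- prev$stages[[nm]]
    can_skip <- !upstream_rerun && !is.null(prev_stage) &&
      identical(prev_stage$status, "done")
    if (can_skip) {
      recorded <- unlist(prev_stage$outputs)
      paths <- file.path(config$out_dir, names(recorded))
      # surface outputs live one level down
      paths[!file.exists(paths)] <- file.path(files$surfaces,
        names(recorded)[!file.exists(paths)])
      ok <- file.exists(paths) &
        unname(tools::md5sum(paths)) == unname(recorded)
      if (all(ok)) {
        say("stage %s: up to date, skipped", nm)
        bodies[[nm]]$load(st, files)
        manifest$stages[[nm]] <- list(status = "skipped",
          outputs = prev_stage$outputs)
        next
      }
      manifest$stages[[nm]] <- list(status = "failed",
        error = sprintf("stage '%s': recorded outputs modified on disk (%s)",
          nm, paste(names(recorded)[!ok], collapse = ", ")))
      for (later in stage_order[-seq_len(si)]) {
        manifest$stages[[later]] <- list(status = "stale")
      }
      finish()
      abort(manifest$stages[[nm]]$error)
    }
    upstream_rerun <- TRUE
    say("stage %s", nm)
    res <- tryCatch(
      counting(bodies[[nm]]$run(st, files)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      manifest$stages[[nm]] <- list(status = "failed",
        error = sprintf("stage '%s': %s", nm, conditionMessage(res)))
      for (later in stage_order[-seq_len(si)]) {
        manifest$stages[[later]] <- list(status = "stale")
      }
      finish()
      abort(manifest$stages[[nm]]$error)
    }
    manifest$stages[[nm]] <- res
  }
  invisible(finish())
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 12)), tmp)
  unname(tools::md5sum(tmp))
}

pipeline_stage_bodies <- function() {
  list(
    simulate = list(
      run = function(st, files) {
        cfg <- st$config
        st$net <- generate_street_network(cfg$city)
        st$dens <- generate_density_raster(cfg$city)
        st$layers <- list(
          intersections = generate_point_layer("intersections", st$dens, st$net, cfg$city),
          transit = generate_point_layer("transit", st$dens, st$net, cfg$city),
          open_space = generate_point_layer("open_space", st$dens, st$net, cfg$city)
        )
        gen <- generate_cohort(cfg$cohort, st$dens, NULL)
        st$cohort <- gen$cohort
        write_geojson_network(st$net, files$network)
        write_ascii_grid(st$dens, files$density)
        for (k in names(st$layers)) {
          write_geojson_points(st$layers[[k]], files$layers[[k]])
        }
        write_table_csv(st$cohort, files$cohort)
        jsonlite::write_json(gen$truth[c("true_beta", "gamma_shape", "seeds")],
          files$truth, auto_unbox = TRUE, digits = NA)
        list(status = "done", outputs = checksums(c(files$network,
          files$density, files$layers, files$cohort, files$truth)))
      },
      load = function(st, files) {
        st$net <- read_geojson_network(files$network)
        st$dens <- read_ascii_grid(files$density)
        st$dens$units <- "residents/km^2"
        st$layers <- lapply(stats::setNames(nm = names(files$layers)), function(k) {
          read_geojson_points(files$layers[[k]], st$net$window, kind = k)
        })
        st$cohort <- read_table_csv(files$cohort)
      }
    ),
    intensity = list(
      run = function(st, files) {
        cfg <- st$config
        dir.create(files$surfaces, showWarnings = FALSE)
        st$bws <- layer_bandwidths(st$layers, cfg$exposure)
        surface_paths <- character(0)
        for (k in names(st$layers)) {
          for (p in names(st$bws[[k]])) {
            if (is.null(st$bws[[k]][[p]])) next
            s <- suppressWarnings(kernel_intensity_surface(
              st$layers[[k]], st$bws[[k]][[p]],
              cell_size_m = cfg$exposure$cell_size_m))
            sp <- file.path(files$surfaces, sprintf("%s_%s.asc", k, p))
            write_ascii_grid(s, sp)
            surface_paths <- c(surface_paths, sp, paste0(sp, ".json"))
          }
        }
        list(status = "done", outputs = checksums(surface_paths))
      },
      load = function(st, files) {
        st$bws <- NULL # recomputed inside build_exposure_matrix if needed
      }
    ),
    exposure = list(
      run = function(st, files) {
        cfg <- st$config
        st$exposures <- build_exposure_matrix(st$cohort, st$layers, st$net,
          st$dens, cfg$exposure)
        write_table_csv(st$exposures, files$exposures)
        write_table_csv(exposure_summary(st$exposures), files$exposure_summary)
        err <- attr(st$exposures, "errors")
        list(status = "done",
          skipped_children = if (is.null(err)) 0L else nrow(err),
          outputs = checksums(c(files$exposures, files$exposure_summary)))
      },
      load = function(st, files) {
        st$exposures <- read_table_csv(files$exposures)
      }
    ),
    mvpa = list(
      run = function(st, files) {
        cfg <- st$config
        cohort <- st$cohort
        if (!is.null(cfg$exposure_effect)) {
          ef <- cfg$exposure_effect
          expo <- st$exposures |>
            filter(.data$kind == ef$kind, .data$measure == ef$measure,
              .data$distance_m == ef$distance_m) |>
            select("child_id", exposure_value = "value")
          cohort <- dplyr::inner_join(cohort, expo, by = "child_id")
          cohort$true_exposure <- cohort$exposure_value
          cohort$exposure_value <- NULL
          cc <- cfg$cohort
          for (g in names(cc$true_beta)) {
            cc$true_beta[[g]][["exposure"]] <- log(ef$exp_beta)
          }
          eta <- recompute_linear_predictor(cohort, cc)
          cohort$mvpa_min_per_day <- with_seed(
            stream_seed(cfg$seed, "mvpa_effect"), {
              rgamma(nrow(cohort), shape = cc$gamma_shape,
                rate = cc$gamma_shape / exp(eta))
            })
        }
        if (cfg$use_epochs) {
          epochs <- bind_rows(lapply(seq_len(nrow(cohort)), function(i) {
            generate_epoch_counts(cohort$child_id[i],
              habitual_mvpa_min_per_day = cohort$mvpa_min_per_day[i],
              n_days = cfg$epoch_days,
              config = epoch_config(noise = "none"))
          }))
          write_table_csv(epochs, files$epochs)
          hab <- process_epochs(epochs)
          cohort <- cohort |>
            select(-"mvpa_min_per_day") |>
            left_join(hab |> select("child_id", "mvpa_min_per_day", "included"),
              by = "child_id") |>
            filter(.data$included) |>
            select(-"included")
        }
        st$cohort <- cohort
        write_table_csv(cohort, files$mvpa)
        list(status = "done", outputs = checksums(files$mvpa))
      },
      load = function(st, files) {
        st$cohort <- read_table_csv(files$mvpa)
      }
    ),
    fit = list(
      run = function(st, files) {
        fits <- fit_basic_models(st$cohort)
        write_table_csv(attr(fits, "report"), files$basic_fit)
        pattern <- run_pattern_analysis(st$cohort, st$exposures)
        write_table_csv(as_tibble(pattern), files$pattern)
        list(status = "done",
          outputs = checksums(c(files$basic_fit, files$pattern)))
      },
      load = function(st, files) invisible(NULL)
    )
  )
}

recompute_linear_predictor <- function(cohort, config) {
  vapply(seq_len(nrow(cohort)), function(i) {
    b <- config$true_beta[[if (cohort$age_group[i] == "school") "school" else "preschool"]]
    b[["intercept"]] +
      b[["age"]] * cohort$age_years[i] +
      b[["bmi_z"]] * cohort$bmi_z[i] +
      b[["weartime"]] * cohort$valid_weartime_h[i] +
      b[["season_spring_summer"]] * (cohort$season[i] == "spring_summer") +
      b[["safety_yes"]] * (cohort$safety_concerns[i] == "yes") +
      b[["isced_low"]] * (cohort$isced[i] == "low") +
      b[["isced_high"]] * (cohort$isced[i] == "high") +
      b[["exposure"]] * cohort$true_exposure[i]
  }, numeric(1))
}

checksums <- function(paths) {
  paths <- unname(unlist(paths))
  md5 <- tools::md5sum(paths)
  stats::setNames(as.list(unname(md5)), basename(paths))
}
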