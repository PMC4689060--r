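# ---- accelerometer epoch processing -------------------------------------

# locale-independent weekday label for Dates
weekday_label <- function(d) {
  c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")[as.POSIXlt(d)$wday + 1L]
}

is_weekend_label <- function(wd) wd %in% c("Sat", "Sun")

#' Detect non-wear epochs
#'
#' Flags every epoch belonging to a maximal run of at least
#' `min_zero_run_min` minutes of consecutive zero counts (default 30 min =
#' 120 fifteen-second epochs) as non-wear. Runs are evaluated within each
#' calendar day; runs shorter than the threshold are kept as wear time, and
#' runs interrupted by a single non-zero epoch are not merged.
#'
#' @param series epoch tibble with columns `child_id`, `date`, `counts`
#'   (rows in time order within child and day).
#' @param min_zero_run_min run-length threshold in minutes.
#' @param epoch_s epoch length in seconds (default 15).
#' @return logical vector, TRUE for non-wear epochs.
#' @export
detect_nonwear <- function(series, min_zero_run_min = 30, epoch_s = 15) {
  if (nrow(series) == 0L) {
    return(logical(0))
  }
  min_run <- round(min_zero_run_min * 60 / epoch_s)
  key <- paste(series$child_id, series$date)
  out <- logical(nrow(series))
  for (idx in split(seq_len(nrow(series)), key)) {
    z <- series$counts[idx] == 0
    r <- rle(z)
    flag <- rep(r$values & r$lengths >= min_run, r$lengths)
    out[idx] <- flag
  }
  out
}

#' Summarize epoch series into day records
#'
#' Applies non-wear exclusion, classifies moderate-to-vigorous epochs with
#' the 2298 counts-per-minute cut-off, and applies the 8-hour wear-time
#' validity rule. On 15-s epochs the cut-off corresponds to
#' `ceiling(2298 / 4) = 575` counts per epoch (counts are integers, so the
#' cpm threshold is conservative at the epoch scale). Alternatively the
#' series can be re-integrated to 60-s epochs before classification.
#'
#' @param series epoch tibble (`child_id`, `timestamp`, `date`, `weekday`,
#'   `counts`).
#' @param cutoff_cpm MVPA cut-off in counts per minute (default 2298).
#' @param min_weartime_h daily validity threshold in hours (default 8).
#' @param min_zero_run_min non-wear run threshold in minutes (default 30).
#' @param reintegrate_60s classify on 60-s re-integrated epochs instead of
#'   scaled 15-s epochs (default FALSE).
#' @return tibble with one row per child-day: `weartime_h`, `mvpa_min`,
#'   `is_weekend`, `is_valid`.
#' @export
summarize_days <- function(series, cutoff_cpm = 2298, min_weartime_h = 8,
                           min_zero_run_min = 30, reintegrate_60s = FALSE) {
  if (nrow(series) == 0L) {
    return(tibble(child_id = character(), date = as.Date(character()),
      weekday = character(), weartime_h = numeric(), mvpa_min = numeric(),
      is_weekend = logical(), is_valid = logical()))
  }
  nonwear <- detect_nonwear(series, min_zero_run_min = min_zero_run_min)
  series$worn <- !nonwear
  cutoff_epoch <- ceiling(cutoff_cpm / 4)
  if (!reintegrate_60s) {
    series$is_mvpa <- series$worn & series$counts >= cutoff_epoch
    daily <- series |>
      group_by(.data$child_id, .data$date, .data$weekday) |>
      summarise(
        weartime_h = sum(.data$worn) * 15 / 3600,
        mvpa_min = sum(.data$is_mvpa) / 4,
        .groups = "drop"
      )
  } else {
    series$minute <- as.POSIXct(floor(as.numeric(series$timestamp) / 60) * 60,
      tz = "UTC", origin = "1970-01-01")
    daily <- series |>
      group_by(.data$child_id, .data$date, .data$weekday, .data$minute) |>
      summarise(
        worn_any = any(.data$worn),
        worn_n = sum(.data$worn),
        total = sum(.data$counts[.data$worn]),
        .groups = "drop_last"
      ) |>
      summarise(
        weartime_h = sum(.data$worn_n) * 15 / 3600,
        mvpa_min = sum(.data$worn_any & .data$total >= cutoff_cpm),
        .groups = "drop"
      )
  }
  daily |>
    mutate(
      is_weekend = is_weekend_label(.data$weekday),
      is_valid = .data$weartime_h >= min_weartime_h
    ) |>
    arrange(.data$child_id, .data$date)
}

#' Habitual MVPA with the inclusion rule
#'
#' A child is included when some window of at least `min_consecutive_days`
#' consecutive calendar days is entirely valid and contains at least one
#' weekend day (Saturday or Sunday). Habitual MVPA is the average over all
#' valid days (not only the qualifying window; set
#' `average = "qualifying_window"` for the stricter variant). Mean valid-day
#' wear time is reported for use as a model covariate.
#'
#' @param day_summaries output of [summarize_days()].
#' @param min_consecutive_days length of the required all-valid run.
#' @param average which days enter the MVPA average.
#' @return tibble with one row per child: `mvpa_min_per_day`,
#'   `mean_valid_weartime_h`, `n_valid_days`, `included`.
#' @export
habitual_mvpa <- function(day_summaries, min_consecutive_days = 3,
                          average = c("valid_days", "qualifying_window")) {
  average <- match.arg(average)
  day_summaries |>
    group_by(.data$child_id) |>
    summarise(
      res = list(habitual_one(.data$date, .data$is_valid, .data$is_weekend,
        .data$mvpa_min, .data$weartime_h, min_consecutive_days, average)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
}

habitual_one <- function(date, is_valid, is_weekend, mvpa_min, weartime_h,
                         min_run, average) {
  ord <- order(date)
  date <- date[ord]; is_valid <- is_valid[ord]
  is_weekend <- is_weekend[ord]; mvpa_min <- mvpa_min[ord]
  weartime_h <- weartime_h[ord]
  # maximal runs of consecutive calendar dates that are all valid
  vidx <- which(is_valid)
  included <- FALSE
  qualifying <- integer(0)
  if (length(vidx) >= min_run) {
    brk <- c(0, which(diff(as.numeric(date[vidx])) != 1), length(vidx))
    for (k in seq_len(length(brk) - 1)) {
      run <- vidx[(brk[k] + 1):brk[k + 1]]
      if (length(run) >= min_run && any(is_weekend[run])) {
        included <- TRUE
        qualifying <- union(qualifying, run)
      }
    }
  }
  avg_idx <- if (average == "valid_days") vidx else sort(qualifying)
  list(
    mvpa_min_per_day = if (length(avg_idx)) mean(mvpa_min[avg_idx]) else NA_real_,
    mean_valid_weartime_h = if (length(vidx)) mean(weartime_h[vidx]) else NA_real_,
    n_valid_days = length(vidx),
    included = included
  )
}

#' Epochs to per-child habitual MVPA
#'
#' Convenience wrapper: [detect_nonwear()] + [summarize_days()] +
#' [habitual_mvpa()] for a long-format epoch table of many children.
#'
#' @inheritParams summarize_days
#' @inheritParams habitual_mvpa
#' @return per-child tibble from [habitual_mvpa()].
#' @export
process_epochs <- function(series, cutoff_cpm = 2298, min_weartime_h = 8,
                           min_zero_run_min = 30, reintegrate_60s = FALSE,
                           min_consecutive_days = 3,
                           average = c("valid_days", "qualifying_window")) {
  habitual_mvpa(
    summarize_days(series, cutoff_cpm = cutoff_cpm,
      min_weartime_h = min_weartime_h, min_zero_run_min = min_zero_run_min,
      reintegrate_60s = reintegrate_60s),
    min_consecutive_days = min_consecutive_days,
    average = average
  )
}
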