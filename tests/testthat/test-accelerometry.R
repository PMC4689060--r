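# non-wear detection, day summaries, inclusion rule

epoch_series <- function(counts, date = as.Date("2007-10-01"),
                         child = "c1", start_hour = 7) {
  n <- length(counts)
  tibble::tibble(
    child_id = child,
    timestamp = as.POSIXct(date, tz = "UTC") + start_hour * 3600 +
      15 * (seq_len(n) - 1),
    date = date,
    weekday = kernelhoods:::weekday_label(date),
    counts = as.integer(counts)
  )
}

test_that("non-wear flags runs of at least 120 zero epochs, never shorter runs", {
  s120 <- epoch_series(c(rep(100, 10), rep(0, 120), rep(100, 10)))
  m <- detect_nonwear(s120)
  expect_equal(sum(m), 120)
  expect_true(all(m[11:130]))
  s119 <- epoch_series(c(rep(100, 10), rep(0, 119), rep(100, 10)))
  expect_equal(sum(detect_nonwear(s119)), 0)
  # two 60-zero runs split by one active epoch are not merged
  split_runs <- epoch_series(c(rep(0, 60), 300, rep(0, 60)))
  expect_equal(sum(detect_nonwear(split_runs)), 0)
  # empty series
  expect_length(detect_nonwear(epoch_series(integer(0))), 0)
})

test_that("non-wear detection is idempotent", {
  s <- epoch_series(c(rep(100, 50), rep(0, 200), rep(600, 50), rep(0, 119)))
  m1 <- detect_nonwear(s)
  s2 <- s
  s2$counts[m1] <- 0L # masking already-flagged epochs changes nothing
  expect_identical(detect_nonwear(s2), m1)
})

test_that("the MVPA cut-off scales 2298 cpm to a 575-count epoch boundary", {
  s <- epoch_series(c(575, 574, rep(100, 1918))) # exactly 8 h of epochs
  d <- summarize_days(s)
  expect_equal(d$mvpa_min, 0.25) # one 15-s epoch
  expect_equal(d$weartime_h, 8)
  expect_true(d$is_valid) # 8 h exactly satisfies "at least 8 h"
  # all-zero day: no weartime, invalid
  z <- summarize_days(epoch_series(rep(0, 1920)))
  expect_equal(z$weartime_h, 0)
  expect_false(z$is_valid)
  # 60-s reintegration mode: four epochs of 574 sum to 2296 < 2298
  r <- summarize_days(epoch_series(c(rep(574, 4), rep(575, 4), rep(100, 1912))),
    reintegrate_60s = TRUE)
  expect_equal(r$mvpa_min, 1)
})

test_that("MVPA minutes exclude non-wear and respect wear-time accounting", {
  # a 30-min zero run inside an otherwise active day
  counts <- c(rep(700, 1920), rep(0, 120), rep(100, 1800))
  d <- summarize_days(epoch_series(counts))
  expect_equal(d$weartime_h, (1920 + 1800) * 15 / 3600)
  expect_equal(d$mvpa_min, 1920 / 4)
  expect_lte(d$mvpa_min, d$weartime_h * 60)
})

test_that("inclusion needs three consecutive valid days with a weekend day", {
  mk <- function(dates, valid = TRUE) {
    tibble::tibble(
      child_id = "c", date = dates,
      weekday = kernelhoods:::weekday_label(dates),
      weartime_h = ifelse(valid, 10, 2),
      mvpa_min = 55,
      is_weekend = kernelhoods:::is_weekend_label(kernelhoods:::weekday_label(dates)),
      is_valid = valid
    )
  }
  fri <- as.Date("2007-10-05") # Friday
  # Fri + Sat + Sun valid -> included
  expect_true(habitual_mvpa(mk(fri + 0:2))$included)
  # Mon-Wed valid only -> excluded (no weekend day)
  mon <- as.Date("2007-10-01")
  expect_false(habitual_mvpa(mk(mon + 0:2))$included)
  # Sat + Sun valid only -> excluded (< 3 consecutive days)
  expect_false(habitual_mvpa(mk(fri + 1:2))$included)
  # a single invalid day breaks the run
  days <- dplyr::bind_rows(mk(fri + 0:1), mk(fri + 2, valid = FALSE), mk(fri + 3:4))
  expect_false(habitual_mvpa(days)$included)
  # averaging covers all valid days, not only the qualifying window
  week <- mk(fri + 0:4)
  week$mvpa_min <- c(40, 50, 60, 70, 80)
  h <- habitual_mvpa(week)
  expect_equal(h$mvpa_min_per_day, mean(c(40, 50, 60, 70, 80)))
  expect_equal(h$n_valid_days, 5)
})

test_that("adding MVPA-level epochs to a valid day never lowers habitual MVPA", {
  base <- generate_epoch_counts("c1", 40, n_days = 4,
    start_date = as.Date("2007-10-05"))
  h0 <- process_epochs(base)$mvpa_min_per_day
  more <- base
  light <- which(more$counts < 575)
  more$counts[light[1:200]] <- 800L
  h1 <- process_epochs(more)$mvpa_min_per_day
  expect_gte(h1, h0)
})

test_that("round trip: deterministic epochs reproduce the configured MVPA exactly", {
  for (target in c(25, 60.25, 90)) {
    ep <- generate_epoch_counts("c1", target, n_days = 5,
      start_date = as.Date("2007-10-04"))
    expect_equal(process_epochs(ep)$mvpa_min_per_day, target)
  }
  # with an injected 30-min bout the weartime drops but MVPA is preserved
  ep <- generate_epoch_counts("c1", 45, n_days = 4,
    start_date = as.Date("2007-10-05"),
    config = epoch_config(nonwear_bouts = list(
      list(day = 1, start_hour = 10, duration_min = 30))))
  d <- summarize_days(ep)
  expect_equal(d$weartime_h[1], 14 - 0.5)
  expect_equal(process_epochs(ep)$mvpa_min_per_day, 45)
  # a 29.75-min bout is kept as weartime
  ep2 <- generate_epoch_counts("c1", 45, n_days = 1,
    start_date = as.Date("2007-10-05"),
    config = epoch_config(nonwear_bouts = list(
      list(day = 1, start_hour = 10, duration_min = 29.75))))
  expect_equal(summarize_days(ep2)$weartime_h, 14)
})
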