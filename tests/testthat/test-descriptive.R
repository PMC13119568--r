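origin_monday <- as.POSIXct("2024-01-08 00:00:00", tz = "UTC")  # a Monday

fake_participant <- function(id, event_secs, start_time = origin_monday) {
  list(series = hr_series(id, numeric(0), numeric(0), age = 22,
                          start_time = start_time),
       events = stress_event_log(id, event_secs, start_time = start_time))
}

test_that("single-participant counts and statistics are exact", {
  cohort <- list(P1 = fake_participant("P1", c(3600, 7200, 10800)))
  s <- summarize_cohort(cohort)
  expect_equal(s$total_events, 3)
  expect_equal(s$events_per_participant_mean, 3)
  expect_equal(s$events_per_participant_median, 3)
  expect_equal(s$events_per_participant_sd, 0)
})

test_that("weekday and hourly counts conserve the total and use local time", {
  # Monday 01:30, Monday 18:59, Tuesday 00:00, Saturday 12:00
  secs <- c(1.5 * 3600, 18 * 3600 + 59 * 60, 24 * 3600, 5 * 86400 + 12 * 3600)
  cohort <- list(P1 = fake_participant("P1", secs[1:2]),
                 P2 = fake_participant("P2", secs[3:4]))
  s <- summarize_cohort(cohort)
  expect_equal(sum(s$weekday_counts), s$total_events)
  expect_equal(sum(s$hourly_counts), s$total_events)
  expect_equal(unname(s$weekday_counts[c("Mon", "Tue", "Sat")]), c(2, 1, 1))
  # 18:59 bins to hour 18 by truncation
  expect_equal(unname(s$hourly_counts["18"]), 1)
  expect_equal(unname(s$hourly_counts["01"]), 1)
})

test_that("per-day averages split school days and weekend days", {
  avg <- weekday_daily_averages(c(240, 240, 240, 240, 240, 157, 156))
  expect_equal(avg$school_day, 1200 / 5)
  expect_equal(avg$weekend_day, 313 / 2)
})

test_that("stress-window heart-rate statistics pool all window samples", {
  cohort <- list(P1 = fake_participant("P1", 3600))
  w <- event_window("P1", "stress", 3600, offset = -2:2,
                    values = c(88, 90, 92, 94, 96), nominal_length = 5L)
  s <- summarize_cohort(cohort, stress_windows = list(w))
  expect_equal(s$stress_hr_mean, 92)
  expect_equal(s$stress_hr_median, 92)
  expect_equal(s$stress_hr_sd, sd(c(88, 90, 92, 94, 96)))
})

test_that("hourly trend detects a forced monotone rise", {
  counts <- numeric(24)
  counts[7:19] <- seq(2, 146, length.out = 13)  # rising 06:00 -> 18:00
  r <- hourly_trend(counts, span = 6:18)
  expect_identical(r$direction, "increasing")
  expect_lt(r$p_value, 0.05)
  expect_identical(hourly_trend(rep(3, 24), span = 6:18)$statistic, 0)
  expect_error(hourly_trend(counts, span = 1:2), "4 hours")
  expect_error(hourly_trend(counts, span = 20:28), "0..23")
})

test_that("a sinusoidal diurnal event rate yields opposite trends on the two spans", {
  hits_up <- hits_down <- 0
  for (seed in 1:50) {
    set.seed(seed)
    hours <- 0:23
    rate <- 8 * (1 + sin(2 * pi * (hours - 12) / 24))  # peak at 18:00
    counts <- rpois(24, rate)
    up <- hourly_trend(counts, span = 6:18)
    down <- hourly_trend(counts, span = c(18:23, 0:6))
    hits_up <- hits_up + (up$direction == "increasing")
    hits_down <- hits_down + (down$direction == "decreasing")
  }
  expect_gte(hits_up, 45)    # >= 90% of seeds
  expect_gte(hits_down, 45)
})
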