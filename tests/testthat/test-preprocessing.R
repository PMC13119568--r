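make_series <- function(bpm, age = 22, time = seq_along(bpm) - 1) {
  hr_series("P1", time = time, bpm = bpm, age = age)
}

test_that("range filter applies the printed bounds strictly", {
  r <- filter_artifacts(make_series(c(55, 70, 210), age = 22))  # max = 198
  expect_equal(r$series$bpm, 70)
  expect_equal(r$removed_fraction, 2 / 3)
  expect_equal(r$series$time, 1)  # survivor keeps its timestamp

  # boundary values are kept: "below 60" and "above 220 - age" are strict
  r2 <- filter_artifacts(make_series(c(60, 190), age = 30))
  expect_equal(r2$series$bpm, c(60, 190))
  expect_equal(r2$removed_fraction, 0)

  empty <- filter_artifacts(hr_series("P1", numeric(0), numeric(0), age = 22))
  expect_equal(empty$removed_fraction, 0)
  expect_identical(length(empty$series), 0L)
})

test_that("the filter is idempotent", {
  set.seed(4)
  s <- make_series(runif(500, 30, 250))
  once <- filter_artifacts(s)$series
  twice <- filter_artifacts(once)
  expect_identical(twice$series, once)
  expect_equal(twice$removed_fraction, 0)
})

test_that("removed fraction tracks the synthetic contamination rate", {
  cfg <- sim_config(n_participants = 1, duration = 20000,
                    events_per_participant = 0, artifact_rate = 0.062,
                    seed = 8)
  p <- generate_participant(cfg, "P001", 1)
  r <- filter_artifacts(p$series)
  expect_equal(r$removed_fraction, 0.062, tolerance = 0.005)
})

test_that("stress windows have the stated geometry", {
  s <- make_series(rep(80, 20001), time = 0:20000)
  ev <- stress_event_log("P1", 5000)
  w <- extract_stress_windows(s, ev)
  expect_length(w, 1)
  expect_identical(length(w[[1]]$values), 1201L)       # 10 min both sides at 1 Hz
  expect_equal(range(w[[1]]$offset), c(-600, 600))
  expect_equal(w[[1]]$center_time, 5000)
  expect_identical(w[[1]]$label, "stress")
})

test_that("events near a recording boundary are dropped with a warning", {
  s <- make_series(rep(80, 2001), time = 0:2000)
  expect_warning(w <- extract_stress_windows(s, stress_event_log("P1", 100)),
                 "boundary")
  expect_length(w, 0)
})

test_that("low-coverage windows are dropped; overlapping events both kept", {
  # carve a large gap around the event
  t <- 0:20000
  keep <- !(t > 4500 & t < 5500)
  s <- make_series(rep(80, sum(keep)), time = t[keep])
  expect_warning(w <- extract_stress_windows(s, stress_event_log("P1", 5000)),
                 "coverage")
  expect_length(w, 0)

  s2 <- make_series(rep(80, 20001), time = 0:20000)
  w2 <- extract_stress_windows(s2, stress_event_log("P1", c(5000, 5300)))
  expect_length(w2, 2)  # 300 s apart: overlap permitted
})

test_that("normal windows are disjoint from stress windows and each other", {
  cfg <- sim_config(n_participants = 1, duration = 20000,
                    events_per_participant = 1, artifact_rate = 0, seed = 14)
  p <- generate_participant(cfg, "P001", 1)
  f <- filter_artifacts(p$series)$series
  sw <- extract_stress_windows(f, p$events)
  nw <- sample_normal_windows(f, p$events, n = 1, seed = 101)
  expect_length(nw, 1)
  stress_times <- sw[[1]]$offset + sw[[1]]$center_time
  normal_times <- nw[[1]]$offset + nw[[1]]$center_time
  expect_length(intersect(stress_times, normal_times), 0)

  # reproducible under the same seed, generally different under another
  nw_b <- sample_normal_windows(f, p$events, n = 1, seed = 101)
  expect_identical(nw_b[[1]]$center_time, nw[[1]]$center_time)
  nw_c <- sample_normal_windows(f, p$events, n = 3, seed = 999)
  centers <- vapply(nw_c, `[[`, numeric(1), "center_time")
  expect_true(all(abs(outer(centers, centers, `-`)[lower.tri(diag(3))]) > 1200))
  for (w in nw_c) {
    expect_true(all(abs((w$offset + w$center_time) -
                          p$events$event_times[1]) > 600))
  }
})

test_that("n = 0 and infeasible requests degrade gracefully", {
  s <- make_series(rep(80, 5001), time = 0:5000)
  ev <- stress_event_log("P1", 2500)
  expect_length(sample_normal_windows(s, ev, n = 0, seed = 1), 0)
  expect_warning(
    few <- sample_normal_windows(s, ev, n = 5, seed = 1, max_tries = 500),
    "placed"
  )
  expect_lt(length(few), 5)
})
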