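test_that("config invariants are enforced", {
  expect_error(sim_config(duration = 1000, episode_half_width = 600),
               "duration")
  expect_error(sim_config(artifact_rate = 1), "artifact_rate")
  expect_error(sim_config(normal_alpha = 0.3), "normal_alpha")
  expect_error(sim_config(stress_alpha = 1.7), "stress_alpha")
  expect_error(generate_long_range_noise(1000, alpha = 2, seed = 1), "alpha")
  expect_error(generate_long_range_noise(8, alpha = 1, seed = 1), "n")
})

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- sim_config(n_participants = 2, duration = 7200,
                    events_per_participant = 2, seed = 33)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(sim_config(n_participants = 2, duration = 7200,
                                   events_per_participant = 2, seed = 34))
  expect_false(identical(c1[[1]]$series$bpm, c3[[1]]$series$bpm))
})

test_that("generated noise is standardised and recovers its target exponent", {
  x <- generate_long_range_noise(4096, alpha = 1.0, seed = 5)
  expect_equal(mean(x), 0, tolerance = 1e-10)
  expect_equal(sd(x), 1, tolerance = 1e-10)

  for (target in c(0.5, 1.0, 1.5)) {
    est <- vapply(1:20, function(s) {
      dfa_alpha(generate_long_range_noise(16384, target, seed = s))$alpha
    }, numeric(1))
    expect_equal(mean(est), target, tolerance = 0.05)
  }
})

test_that("artifact-free output stays in physiologic range and events are spaced", {
  cfg <- sim_config(n_participants = 1, duration = 20000,
                    events_per_participant = 3, artifact_rate = 0,
                    seed = 9)
  p <- generate_participant(cfg, "P001", 1)
  expect_identical(length(p$events$event_times), 3L)
  gaps <- diff(p$events$event_times)
  expect_true(all(gaps > 2 * cfg$episode_half_width))
  # noise excursions beyond ~4.5 sd are possible but none should cross the
  # artifact filter bounds for this configuration
  expect_true(all(p$series$bpm >= 60))
  expect_true(all(p$series$bpm <= 220 - cfg$age))
  expect_identical(length(p$series$time), 20000L)
})

test_that("events that cannot be placed without overlap are rejected", {
  cfg <- sim_config(n_participants = 1, duration = 3000,
                    events_per_participant = 5, episode_half_width = 600)
  expect_error(generate_participant(cfg, "P001", 1), "cannot place")
})

test_that("the configured artifact rate is realised in the output", {
  cfg <- sim_config(n_participants = 1, duration = 10000,
                    events_per_participant = 0, artifact_rate = 0.05,
                    seed = 21)
  p <- generate_participant(cfg, "P001", 1)
  out_of_range <- mean(p$series$bpm < 60 | p$series$bpm > 220 - cfg$age)
  expect_equal(out_of_range, 0.05, tolerance = 0.005)
})

test_that("injected stress episodes raise the window mean", {
  cfg <- sim_config(n_participants = 5, duration = 43200,
                    events_per_participant = 4, stress_mean_shift = 8,
                    artifact_rate = 0, seed = 17)
  cohort <- simulate_cohort(cfg)
  stress_means <- normal_means <- c()
  for (p in cohort) {
    f <- filter_artifacts(p$series)$series
    sw <- extract_stress_windows(f, p$events)
    nw <- sample_normal_windows(f, p$events, n = length(sw), seed = 3)
    stress_means <- c(stress_means, vapply(sw, function(w) mean(w$values),
                                           numeric(1)))
    normal_means <- c(normal_means, vapply(nw, function(w) mean(w$values),
                                           numeric(1)))
  }
  expect_gte(length(stress_means), 20)
  expect_gt(mean(stress_means), mean(normal_means))
})

test_that("cohort CSV round-trips through write and read", {
  cfg <- sim_config(n_participants = 2, duration = 3600,
                    events_per_participant = 1, seed = 12)
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort_csv(cohort, dir)
  back <- read_cohort_csv(dir, age = cfg$age)
  expect_identical(names(back), c("P001", "P002"))
  expect_equal(back$P001$series$bpm, cohort$P001$series$bpm,
               tolerance = 1e-5)
  expect_equal(back$P001$series$time, cohort$P001$series$time)
  expect_equal(back$P001$events$event_times, cohort$P001$events$event_times)
})
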