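#' Simulation configuration for a synthetic wearable cohort
#'
#' Defines the statistical structure of the generated recordings: a circadian
#' baseline, long-range-correlated noise with a tunable DFA scaling exponent,
#' out-of-range artifact contamination, and stress episodes that raise both
#' the mean heart rate and the noise persistence around recorded timestamps.
#'
#' Defaults mirror the wearable study design the pipeline targets: 1 Hz
#' sampling of minute-averaged heart rate, 10-minute episode half-width
#' (20-minute windows), a 6.2% artifact rate, age 22, and scaling-exponent
#' targets of 0.61 (non-stress) and 0.63 (stress).
#'
#' @param n_participants Number of participants.
#' @param duration Recording length per participant, seconds.
#' @param sample_interval Sampling interval, seconds (default 1).
#' @param baseline_bpm Mean resting heart rate, bpm.
#' @param circadian_amplitude Amplitude of the 24-h sinusoidal baseline
#'   modulation, bpm (peak late afternoon, trough early morning).
#' @param noise_sd Standard deviation of the correlated noise, bpm.
#' @param normal_alpha Target DFA scaling exponent outside stress episodes,
#'   in `[0.5, 1.5]`.
#' @param stress_alpha Target scaling exponent within stress episodes,
#'   in `[0.5, 1.5]`.
#' @param stress_mean_shift Heart-rate elevation during episodes, bpm.
#' @param episode_half_width Half-width of a stress episode, seconds
#'   (default 600: a 20-minute window).
#' @param events_per_participant Number of stress reports per participant.
#' @param artifact_rate Fraction of samples replaced by out-of-range values
#'   in `[0, 1)`.
#' @param age Participant age in years (sets the artifact bounds and the
#'   `220 - age` filter ceiling).
#' @param seed Master RNG seed; identical config + seed reproduces the
#'   cohort exactly.
#' @param start_time `POSIXct` wall-clock time of the first sample.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_participants = 10,
                       duration = 86400,
                       sample_interval = 1,
                       baseline_bpm = 85,
                       circadian_amplitude = 5,
                       noise_sd = 5,
                       normal_alpha = 0.61,
                       stress_alpha = 0.63,
                       stress_mean_shift = 8,
                       episode_half_width = 600,
                       events_per_participant = 5,
                       artifact_rate = 0.062,
                       age = 22,
                       seed = 1,
                       start_time = as.POSIXct("2024-01-08 00:00:00",
                                               tz = "UTC")) {
  cfg <- list(n_participants = as.integer(n_participants),
              duration = as.double(duration),
              sample_interval = as.double(sample_interval),
              baseline_bpm = as.double(baseline_bpm),
              circadian_amplitude = as.double(circadian_amplitude),
              noise_sd = as.double(noise_sd),
              normal_alpha = as.double(normal_alpha),
              stress_alpha = as.double(stress_alpha),
              stress_mean_shift = as.double(stress_mean_shift),
              episode_half_width = as.double(episode_half_width),
              events_per_participant = as.integer(events_per_participant),
              artifact_rate = as.double(artifact_rate),
              age = as.double(age),
              seed = as.integer(seed),
              start_time = start_time)
  if (cfg$duration <= 2 * cfg$episode_half_width) {
    stop("`duration` must exceed 2 * episode_half_width", call. = FALSE)
  }
  if (cfg$artifact_rate < 0 || cfg$artifact_rate >= 1) {
    stop("`artifact_rate` must be in [0, 1)", call. = FALSE)
  }
  for (nm in c("normal_alpha", "stress_alpha")) {
    if (cfg[[nm]] < 0.5 || cfg[[nm]] > 1.5) {
      stop(sprintf("`%s` must be in [0.5, 1.5]", nm), call. = FALSE)
    }
  }
  if (cfg$age <= 0 || cfg$age >= 120) stop("`age` must be in (0, 120)",
                                           call. = FALSE)
  if (cfg$n_participants < 1L) stop("need at least one participant",
                                    call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d participants x %.0f s @ %g s; baseline ",
                     "%g bpm, alpha %g/%g (normal/stress), shift %g bpm, ",
                     "%d events, artifact rate %g, seed %d\n"),
              x$n_participants, x$duration, x$sample_interval, x$baseline_bpm,
              x$normal_alpha, x$stress_alpha, x$stress_mean_shift,
              x$events_per_participant, x$artifact_rate, x$seed))
  invisible(x)
}

#' Long-range-correlated noise with a target DFA exponent
#'
#' Spectral synthesis: a Gaussian random spectrum is shaped to the power law
#' `S(f) ~ f^(-beta)` with `beta = 2 * alpha - 1`, so that DFA of the
#' inverse transform recovers the scaling exponent `alpha`
#' (`alpha = (beta + 1) / 2`; `alpha = 0.5` is white noise, 1.0 pink noise,
#' 1.5 Brownian-like persistence). The output is standardised to zero mean
#' and unit variance.
#'
#' @param n Series length, >= 16.
#' @param alpha Target scaling exponent in `[0.5, 1.5]`.
#' @param seed RNG seed (required for reproducibility).
#' @return Numeric vector of length `n`, zero mean, unit variance.
#' @export
#' @examples
#' x <- generate_long_range_noise(4096, alpha = 1.0, seed = 7)
#' dfa_alpha(x)$alpha  # near 1
generate_long_range_noise <- function(n, alpha, seed) {
  n <- as.integer(n)
  if (n < 16L) stop("`n` must be >= 16", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0.5 || alpha > 1.5) {
    stop("`alpha` must be a single value in [0.5, 1.5]", call. = FALSE)
  }
  beta <- 2 * alpha - 1
  with_seed(seed, {
    m <- n %/% 2L
    freq <- seq_len(m) / n
    amp <- freq^(-beta / 2)
    re <- stats::rnorm(m) * amp
    im <- stats::rnorm(m) * amp
    spec <- complex(real = re, imaginary = im)
    # hermitian-symmetric spectrum for a real series
    if (n %% 2L == 0L) {
      spec[m] <- complex(real = re[m], imaginary = 0)
      full <- c(complex(real = 0), spec, Conj(rev(spec[-m])))
    } else {
      full <- c(complex(real = 0), spec, Conj(rev(spec)))
    }
    x <- Re(stats::fft(full, inverse = TRUE)) / n
    as.numeric(scale(x))
  })
}

# Place k episode centres in [hw, duration - hw] with pairwise gaps
# > 2 * hw, uniformly at random given the active RNG state.
place_events <- function(k, duration, half_width, sample_interval) {
  if (k == 0L) return(numeric(0))
  min_gap <- 2 * half_width + sample_interval
  lo <- half_width
  hi <- duration - half_width
  slack <- (hi - lo) - (k - 1) * min_gap
  if (slack < 0) {
    stop(sprintf(
      "cannot place %d non-overlapping stress episodes in %.0f s (need > %.0f s)",
      k, duration, 2 * half_width + (k - 1) * min_gap + 2 * half_width),
      call. = FALSE)
  }
  u <- sort(stats::runif(k, 0, slack))
  round(lo + u + (seq_len(k) - 1) * min_gap)
}

#' Generate one participant's recording and event log
#'
#' The clean signal is `baseline + circadian sinusoid + noise_sd * noise`,
#' where the noise has scaling exponent `normal_alpha` except within
#' `episode_half_width` of each stress event, where an independently
#' generated `stress_alpha` segment is spliced in with a 30-sample linear
#' cross-fade and the mean is raised by `stress_mean_shift` (ramped over the
#' same cross-fade). Finally `artifact_rate` of the samples are replaced by
#' out-of-range values drawn uniformly from `[30, 59]` or `[221 - age, 250]`
#' with equal probability.
#'
#' @param config A [sim_config()].
#' @param participant_id Character identifier.
#' @param participant_index Integer used (with `config$seed`) to derive the
#'   participant's RNG stream, so cohorts are reproducible participant by
#'   participant.
#' @return A list with components `series` ([hr_series()]) and `events`
#'   ([stress_event_log()]).
#' @export
generate_participant <- function(config, participant_id,
                                 participant_index = 1L) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round(config$duration / config$sample_interval))
  t <- (seq_len(n) - 1) * config$sample_interval
  pseed <- derive_seed(config$seed, participant_index)
  hw <- config$episode_half_width
  fade_len <- 30L

  events <- with_seed(pseed, {
    place_events(config$events_per_participant, config$duration, hw,
                 config$sample_interval)
  })

  noise <- generate_long_range_noise(n, config$normal_alpha,
                                     seed = derive_seed(pseed, 1L))
  shift <- numeric(n)
  for (j in seq_along(events)) {
    idx <- which(abs(t - events[j]) <= hw)
    seg <- generate_long_range_noise(max(length(idx), 16L),
                                     config$stress_alpha,
                                     seed = derive_seed(pseed, 100L + j))
    seg <- seg[seq_along(idx)]
    w <- rep(1, length(idx))
    ramp <- seq_len(min(fade_len, length(idx) %/% 2L))
    w[ramp] <- ramp / (length(ramp) + 1)
    w[length(idx) + 1L - ramp] <- ramp / (length(ramp) + 1)
    noise[idx] <- (1 - w) * noise[idx] + w * seg
    shift[idx] <- w * config$stress_mean_shift
  }

  hour_of_day <- (as.numeric(format(config$start_time, "%H")) +
                    as.numeric(format(config$start_time, "%M")) / 60 +
                    t / 3600) %% 24
  circ <- config$circadian_amplitude * sin(2 * pi * (hour_of_day - 11) / 24)
  bpm <- config$baseline_bpm + circ + config$noise_sd * noise + shift

  if (config$artifact_rate > 0) {
    bpm <- with_seed(derive_seed(pseed, 2L), {
      n_art <- round(config$artifact_rate * n)
      idx <- sample.int(n, n_art)
      low <- stats::runif(n_art) < 0.5
      vals <- numeric(n_art)
      vals[low] <- stats::runif(sum(low), 30, 59)
      vals[!low] <- stats::runif(sum(!low), 221 - config$age, 250)
      bpm[idx] <- vals
      bpm
    })
  }

  list(
    series = hr_series(participant_id, time = t, bpm = bpm, age = config$age,
                       start_time = config$start_time,
                       sample_interval = config$sample_interval),
    events = stress_event_log(participant_id, events,
                              start_time = config$start_time)
  )
}

#' Generate a full synthetic cohort
#'
#' @param config A [sim_config()].
#' @return A list with one element per participant, each as returned by
#'   [generate_participant()]; names are the participant ids `P001`, ...
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  ids <- sprintf("P%03d", seq_len(config$n_participants))
  out <- lapply(seq_along(ids), function(i) {
    generate_participant(config, ids[i], participant_index = i)
  })
  names(out) <- ids
  out
}

#' Write a cohort to CSV
#'
#' Writes `samples.csv` (`participant_id`, `timestamp` ISO 8601 UTC,
#' `heart_rate_bpm`) and `events.csv` (`participant_id`, `timestamp`) into
#' `dir`.
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt_ts <- function(origin, secs) {
    format(origin + secs, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  samples <- dplyr::bind_rows(lapply(cohort, function(p) {
    tibble::tibble(
      participant_id = p$series$participant_id,
      timestamp = fmt_ts(p$series$start_time, p$series$time),
      heart_rate_bpm = sprintf("%.6f", p$series$bpm)
    )
  }))
  events <- dplyr::bind_rows(lapply(cohort, function(p) {
    tibble::tibble(
      participant_id = p$events$participant_id,
      timestamp = fmt_ts(p$events$start_time, p$events$event_times)
    )
  }))
  sp <- file.path(dir, "samples.csv")
  ep <- file.path(dir, "events.csv")
  utils::write.csv(samples, sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(events, ep, row.names = FALSE, quote = FALSE)
  invisible(c(samples = sp, events = ep))
}

#' Read a cohort from CSV
#'
#' Reads the `samples.csv` / `events.csv` pair written by
#' [write_cohort_csv()] (or exported from a device pipeline with the same
#' schema). The sample schema carries no age, so the age used by the range
#' filter is supplied here.
#'
#' @param dir Directory containing `samples.csv` and `events.csv`.
#' @param age Participant age in years applied to every participant.
#' @return A cohort list (per participant: `series`, `events`).
#' @export
read_cohort_csv <- function(dir, age) {
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             stringsAsFactors = FALSE)
  events <- utils::read.csv(file.path(dir, "events.csv"),
                            stringsAsFactors = FALSE)
  parse_ts <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ",
                                     tz = "UTC")
  ids <- sort(unique(samples$participant_id))
  out <- lapply(ids, function(id) {
    s <- samples[samples$participant_id == id, ]
    ts <- parse_ts(s$timestamp)
    origin <- ts[1L]
    ev <- events[events$participant_id == id, ]
    ev_secs <- if (nrow(ev)) as.numeric(difftime(parse_ts(ev$timestamp),
                                                 origin, units = "secs"))
               else numeric(0)
    list(
      series = hr_series(id, time = as.numeric(difftime(ts, origin,
                                                        units = "secs")),
                         bpm = as.numeric(s$heart_rate_bpm), age = age,
                         start_time = origin),
      events = stress_event_log(id, ev_secs, start_time = origin)
    )
  })
  names(out) <- ids
  out
}
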