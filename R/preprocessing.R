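#' Physiologic range filter
#'
#' Removes artifact samples: heart-rate values below 60 bpm or above the
#' age-predicted maximum `220 - age`. Both bounds are read strictly, so 60
#' and `220 - age` themselves are kept. Timestamps of the surviving samples
#' are unchanged, leaving gaps where artifacts were removed.
#'
#' @param series A [hr_series()] (its `age` field sets the upper bound).
#' @return A list: `series` (the filtered [hr_series()]) and
#'   `removed_fraction` (removed / total; 0 for an empty input).
#' @export
#' @examples
#' s <- hr_series("P1", 0:2, c(55, 70, 210), age = 22)
#' filter_artifacts(s)$removed_fraction  # 2/3
filter_artifacts <- function(series) {
  stopifnot(inherits(series, "hr_series"))
  n <- length(series$time)
  if (n == 0L) {
    return(list(series = series, removed_fraction = 0))
  }
  upper <- 220 - series$age
  keep <- series$bpm >= 60 & series$bpm <= upper
  filtered <- series
  filtered$time <- series$time[keep]
  filtered$bpm <- series$bpm[keep]
  list(series = filtered, removed_fraction = (n - sum(keep)) / n)
}

#' Extract the 20-minute windows around stress reports
#'
#' One window per event, spanning `[event - half_width, event + half_width]`
#' on the filtered series. Windows too close to a recording boundary, or
#' retaining less than `min_coverage` of the expected samples (gaps left by
#' the range filter), are dropped with a warning rather than an error.
#' Events less than `2 * half_width` apart produce overlapping windows;
#' both are kept.
#'
#' @param series A filtered [hr_series()].
#' @param events A [stress_event_log()].
#' @param half_width Window half-width in seconds (default 600: a 20-minute
#'   window, 10 min either side of the report).
#' @param min_coverage Minimum fraction of expected samples a window must
#'   retain (default 0.8).
#' @return A list of [event_window()] objects labelled `"stress"`.
#' @export
extract_stress_windows <- function(series, events, half_width = 600,
                                   min_coverage = 0.8) {
  stopifnot(inherits(series, "hr_series"),
            inherits(events, "stress_event_log"))
  if (!length(series$time)) return(list())
  nominal <- as.integer(2 * half_width / series$sample_interval + 1)
  t0 <- series$time[1L]
  t1 <- series$time[length(series$time)]
  out <- list()
  for (ev in events$event_times) {
    if (ev - half_width < t0 || ev + half_width > t1) {
      warning(sprintf(
        "participant %s: event at %.0f s within %g s of a recording boundary; window dropped",
        series$participant_id, ev, half_width), call. = FALSE)
      next
    }
    idx <- which(series$time >= ev - half_width & series$time <= ev + half_width)
    w <- event_window(series$participant_id, "stress", ev,
                      offset = series$time[idx] - ev,
                      values = series$bpm[idx], nominal_length = nominal)
    if (w$coverage < min_coverage) {
      warning(sprintf(
        "participant %s: stress window at %.0f s has %.0f%% coverage (< %.0f%%); dropped",
        series$participant_id, ev, 100 * w$coverage, 100 * min_coverage),
        call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- w
  }
  out
}

#' Sample balanced non-stress windows
#'
#' Draws `n` windows of the same duration as the stress windows from the
#' non-stress remainder of the recording: window spans must be disjoint from
#' every stress-window span and from each other. Centres are drawn uniformly
#' at random from the eligible times under the given seed; draws failing the
#' coverage threshold do not count. If the eligible time cannot host `n`
#' disjoint windows, as many as possible are returned with a warning.
#'
#' @param series A filtered [hr_series()].
#' @param events The participant's [stress_event_log()] (defines the
#'   excluded spans).
#' @param n Number of windows, normally the participant's retained
#'   stress-window count.
#' @param half_width Window half-width in seconds (default 600).
#' @param seed RNG seed for the placement draws.
#' @param min_coverage Minimum retained-sample fraction (default 0.8).
#' @param max_tries Placement attempts before giving up (default `200 * n`).
#' @return A list of [event_window()] objects labelled `"normal"`.
#' @export
sample_normal_windows <- function(series, events, n, half_width = 600, seed = 1,
                                  min_coverage = 0.8, max_tries = 200 * n) {
  stopifnot(inherits(series, "hr_series"),
            inherits(events, "stress_event_log"))
  n <- as.integer(n)
  if (n == 0L || !length(series$time)) return(list())
  nominal <- as.integer(2 * half_width / series$sample_interval + 1)
  t0 <- series$time[1L]
  t1 <- series$time[length(series$time)]
  lo <- t0 + half_width
  hi <- t1 - half_width
  if (hi <= lo) {
    warning("recording too short for any normal window", call. = FALSE)
    return(list())
  }
  accepted <- numeric(0)
  out <- list()
  # a centre c is eligible iff |c - e| > 2*half_width for every stress event
  # and every accepted centre (closed spans are then disjoint)
  ok_center <- function(c) {
    all(abs(c - events$event_times) > 2 * half_width) &&
      (!length(accepted) || all(abs(c - accepted) > 2 * half_width))
  }
  with_seed(seed, {
    tries <- 0L
    while (length(out) < n && tries < max_tries) {
      tries <- tries + 1L
      c <- round(stats::runif(1, lo, hi) / series$sample_interval) *
        series$sample_interval
      if (c < lo || c > hi || !ok_center(c)) next
      idx <- which(series$time >= c - half_width & series$time <= c + half_width)
      w <- event_window(series$participant_id, "normal", c,
                        offset = series$time[idx] - c,
                        values = series$bpm[idx], nominal_length = nominal)
      if (w$coverage < min_coverage) next
      accepted <- c(accepted, c)
      out[[length(out) + 1L]] <- w
    }
  })
  if (length(out) < n) {
    warning(sprintf(
      "participant %s: placed %d of %d requested normal windows",
      series$participant_id, length(out), n), call. = FALSE)
  }
  out
}
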