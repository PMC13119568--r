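#' Heart-rate series for one participant
#'
#' A `hr_series` holds the 1 Hz (or other fixed-interval) smartwatch signal
#' for a single participant: each sample is the average heart rate over the
#' preceding minute, stamped at 1 s resolution. Timestamps are seconds since
#' `start_time`, strictly increasing but not necessarily gapless (range
#' filtering removes samples in place).
#'
#' @param participant_id Character scalar identifier.
#' @param time Numeric vector of sample times in seconds, strictly increasing.
#' @param bpm Numeric vector of heart-rate values (beats per minute), same
#'   length as `time`.
#' @param age Participant age in years (used by the physiologic range filter,
#'   upper bound `220 - age`).
#' @param start_time `POSIXct` wall-clock origin of `time = 0`. Timestamps are
#'   treated as local clock time for day-of-week/hour summaries.
#' @param sample_interval Nominal sampling interval in seconds (default 1).
#'
#' @return An object of class `hr_series`.
#' @export
#' @examples
#' s <- hr_series("P001", time = 0:9, bpm = rep(72, 10), age = 22)
#' s
hr_series <- function(participant_id, time, bpm, age,
                      start_time = as.POSIXct("2024-01-08 00:00:00", tz = "UTC"),
                      sample_interval = 1) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  time <- as.double(time)
  bpm <- as.double(bpm)
  if (length(time) != length(bpm)) {
    stop("`time` and `bpm` must have the same length", call. = FALSE)
  }
  if (length(time) > 1L && any(diff(time) <= 0)) {
    stop("`time` must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(age) || length(age) != 1L || age <= 0 || age >= 120) {
    stop("`age` must be a single value in (0, 120)", call. = FALSE)
  }
  structure(
    list(participant_id = participant_id, time = time, bpm = bpm,
         age = as.double(age), start_time = start_time,
         sample_interval = as.double(sample_interval)),
    class = "hr_series"
  )
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> participant %s: %d samples", x$participant_id,
              length(x$time)))
  if (length(x$time)) {
    cat(sprintf(" over %.0f s, bpm range [%.1f, %.1f]",
                diff(range(x$time)), min(x$bpm), max(x$bpm)))
  }
  cat(sprintf(", age %g\n", x$age))
  invisible(x)
}

#' @export
length.hr_series <- function(x) length(x$time)

#' Self-reported stress event log for one participant
#'
#' Event times are seconds since the series `start_time`, sorted ascending.
#' Each event anchors a 20-minute stress window (10 min either side by
#' default).
#'
#' @param participant_id Character scalar identifier.
#' @param event_times Numeric vector of event times in seconds; sorted on
#'   construction.
#' @param start_time `POSIXct` wall-clock origin shared with the series.
#' @return An object of class `stress_event_log`.
#' @export
stress_event_log <- function(participant_id, event_times,
                             start_time = as.POSIXct("2024-01-08 00:00:00",
                                                     tz = "UTC")) {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  event_times <- sort(as.double(event_times))
  structure(
    list(participant_id = participant_id, event_times = event_times,
         start_time = start_time),
    class = "stress_event_log"
  )
}

#' @export
print.stress_event_log <- function(x, ...) {
  cat(sprintf("<stress_event_log> participant %s: %d events\n",
              x$participant_id, length(x$event_times)))
  invisible(x)
}

#' @export
length.stress_event_log <- function(x) length(x$event_times)

#' A labeled fixed-duration signal segment
#'
#' The unit of feature extraction: the samples falling inside a 20-minute
#' span centred on a stress report (`label = "stress"`) or on a randomly
#' placed non-stress time (`label = "normal"`). `offset` holds each sample's
#' time relative to the window centre, so the post-event half is
#' `offset >= 0`.
#'
#' @param participant_id Character scalar.
#' @param label `"stress"` or `"normal"`.
#' @param center_time Window centre in seconds since the series origin.
#' @param offset Numeric vector, sample time minus `center_time`.
#' @param values Heart-rate values at those offsets.
#' @param nominal_length Expected sample count for a gapless window.
#' @return An object of class `event_window`.
#' @export
event_window <- function(participant_id, label, center_time, offset, values,
                         nominal_length = 1201L) {
  label <- match.arg(label, c("stress", "normal"))
  stopifnot(length(offset) == length(values))
  structure(
    list(participant_id = participant_id, label = label,
         center_time = as.double(center_time), offset = as.double(offset),
         values = as.double(values),
         nominal_length = as.integer(nominal_length),
         coverage = length(values) / nominal_length),
    class = "event_window"
  )
}

#' @export
print.event_window <- function(x, ...) {
  cat(sprintf("<event_window> %s %s @ %.0f s: %d/%d samples (%.0f%% coverage)\n",
              x$participant_id, x$label, x$center_time, length(x$values),
              x$nominal_length, 100 * x$coverage))
  invisible(x)
}

#' Flatten a list of event windows to a long-format tibble
#'
#' Columns: `participant_id`, `window_id`, `label`, `center_time`,
#' `offset_s`, `heart_rate_bpm` — the on-disk window layout.
#'
#' @param windows List of [event_window()] objects.
#' @return A tibble with one row per retained sample.
#' @export
windows_to_table <- function(windows) {
  if (!length(windows)) {
    return(tibble::tibble(participant_id = character(), window_id = character(),
                          label = character(), center_time = double(),
                          offset_s = double(), heart_rate_bpm = double()))
  }
  dplyr::bind_rows(lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    tibble::tibble(
      participant_id = w$participant_id,
      window_id = sprintf("%s_%s_%03d", w$participant_id, w$label, i),
      label = w$label, center_time = w$center_time,
      offset_s = w$offset, heart_rate_bpm = w$values
    )
  }))
}
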