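#' Cohort-level descriptive summary
#'
#' Event counts overall, per participant, by weekday and by hour of day,
#' plus the pooled heart-rate distribution inside the stress windows.
#' Weekday/hour assignment uses each event's local wall-clock timestamp
#' (`start_time + event seconds`); hours are binned by truncation, the week
#' starts Monday and the weekend is Saturday + Sunday.
#'
#' @param cohort A cohort list (per participant: `series`, `events`), e.g.
#'   from [simulate_cohort()] or [read_cohort_csv()].
#' @param stress_windows Optional list of stress [event_window()]s whose
#'   pooled samples give the stress heart-rate statistics.
#' @return An object of class `cohort_summary`: `total_events`,
#'   `n_participants`, `events_per_participant_mean/sd/median`,
#'   `weekday_counts` (Mon..Sun), `hourly_counts` (hour 0..23),
#'   `stress_hr_mean/sd/median` (NA without windows).
#' @export
summarize_cohort <- function(cohort, stress_windows = NULL) {
  stopifnot(length(cohort) >= 1L)
  per_part <- vapply(cohort, function(p) length(p$events$event_times),
                     numeric(1))
  total <- sum(per_part)
  wd <- integer(7)
  names(wd) <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  hr <- integer(24)
  names(hr) <- sprintf("%02d", 0:23)
  for (p in cohort) {
    if (!length(p$events$event_times)) next
    ts <- p$events$start_time + p$events$event_times
    w <- as.integer(format(ts, "%u"))          # 1 = Monday
    h <- as.integer(format(ts, "%H"))          # truncation binning
    wd <- wd + tabulate(w, 7)
    hr <- hr + tabulate(h + 1L, 24)
  }
  shr <- if (length(stress_windows)) {
    unlist(lapply(stress_windows, `[[`, "values"))
  } else numeric(0)
  structure(
    list(total_events = total, n_participants = length(cohort),
         events_per_participant_mean = total / length(cohort),
         events_per_participant_sd = if (length(per_part) > 1)
           stats::sd(per_part) else 0,
         events_per_participant_median = stats::median(per_part),
         weekday_counts = wd, hourly_counts = hr,
         stress_hr_mean = if (length(shr)) mean(shr) else NA_real_,
         stress_hr_sd = if (length(shr) > 1) stats::sd(shr) else NA_real_,
         stress_hr_median = if (length(shr)) stats::median(shr) else NA_real_),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d events from %d participants (mean %.1f, sd %.2f, median %g)\n",
              x$total_events, x$n_participants, x$events_per_participant_mean,
              x$events_per_participant_sd, x$events_per_participant_median))
  avg <- weekday_daily_averages(x$weekday_counts)
  cat(sprintf("  weekday/weekend events per day: %.1f / %.1f\n",
              avg$school_day, avg$weekend_day))
  if (is.finite(x$stress_hr_mean)) {
    cat(sprintf("  stress-window HR: mean %.1f, sd %.2f, median %.2f bpm\n",
                x$stress_hr_mean, x$stress_hr_sd, x$stress_hr_median))
  }
  invisible(x)
}

#' Per-day event averages for school days and weekend days
#'
#' Splits the weekday counts (Mon..Sun) into the five school days and the
#' two weekend days and reports events per day for each, e.g. counts of
#' 1200 school-day and 313 weekend events give 240 and 156.5.
#'
#' @param weekday_counts Numeric vector of 7 counts, Monday first.
#' @return A list: `school_day`, `weekend_day`, `school_total`,
#'   `weekend_total`.
#' @export
weekday_daily_averages <- function(weekday_counts) {
  stopifnot(length(weekday_counts) == 7L)
  school <- sum(weekday_counts[1:5])
  weekend <- sum(weekday_counts[6:7])
  list(school_day = school / 5, weekend_day = weekend / 2,
       school_total = school, weekend_total = weekend)
}

#' Trend in hourly event counts over an hour span
#'
#' Applies the Mann-Kendall test to the hourly counts restricted to a span
#' of hours, e.g. `6:18` for the morning-to-evening rise.
#'
#' @param hourly_counts Numeric vector of 24 counts (hour 0..23).
#' @param span Integer vector of hours within 0..23, length >= 4, in the
#'   order to be tested.
#' @return An `mk_result`, see [mann_kendall()].
#' @export
hourly_trend <- function(hourly_counts, span) {
  stopifnot(length(hourly_counts) == 24L)
  span <- as.integer(span)
  if (any(span < 0L | span > 23L)) stop("`span` hours must be in 0..23",
                                        call. = FALSE)
  if (length(span) < 4L) stop("`span` must cover at least 4 hours",
                              call. = FALSE)
  mann_kendall(hourly_counts[span + 1L])
}
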