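#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. Input is either a
#' simulation config (`sim`) or a directory holding `samples.csv` /
#' `events.csv` (`input_dir` + `age`).
#'
#' @param sim A [sim_config()], or `NULL` when reading from disk.
#' @param input_dir Directory with `samples.csv` / `events.csv`
#'   (ignored when `sim` is given).
#' @param age Age for the range filter when reading from disk.
#' @param half_width Window half-width, seconds (default 600).
#' @param min_coverage Minimum window coverage fraction (default 0.8).
#' @param acf_max_lag Largest ACF lag (default 600, half the nominal
#'   1201-sample window).
#' @param band ACF significance band: `"white"` or `"bartlett"`.
#' @param peak_mode ACF peak counting: `"all"` or `"significant"`.
#' @param dfa_span `"post_event"` (the 300 samples after the window centre,
#'   the 5 minutes after the report) or `"full"` (all window samples).
#' @param dfa_span_samples Length of the post-event DFA segment
#'   (default 300).
#' @param alpha_level Significance level (default 0.05).
#' @param seed Master seed for normal-window placement (and simulation when
#'   `sim` carries no seed of its own).
#' @param output_dir Optional directory; when given, all artifacts are
#'   written there.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL, age = NULL,
                            half_width = 600, min_coverage = 0.8,
                            acf_max_lag = 600,
                            band = c("white", "bartlett"),
                            peak_mode = c("all", "significant"),
                            dfa_span = c("post_event", "full"),
                            dfa_span_samples = 300,
                            alpha_level = 0.05, seed = 1,
                            output_dir = NULL) {
  band <- match.arg(band)
  peak_mode <- match.arg(peak_mode)
  dfa_span <- match.arg(dfa_span)
  if (is.null(sim) && is.null(input_dir)) {
    stop("provide either `sim` or `input_dir`", call. = FALSE)
  }
  if (!is.null(input_dir) && is.null(sim) && is.null(age)) {
    stop("`age` is required when reading a cohort from disk", call. = FALSE)
  }
  structure(
    list(sim = sim, input_dir = input_dir, age = age,
         half_width = half_width, min_coverage = min_coverage,
         acf_max_lag = as.integer(acf_max_lag), band = band,
         peak_mode = peak_mode, dfa_span = dfa_span,
         dfa_span_samples = as.integer(dfa_span_samples),
         alpha_level = alpha_level, seed = as.integer(seed),
         output_dir = output_dir),
    class = "pipeline_config"
  )
}

# samples feeding DFA for one window: the post-event segment (offset >= 0)
# or the full window
dfa_input <- function(window, config) {
  if (config$dfa_span == "full") return(window$values)
  v <- window$values[window$offset >= 0]
  v[seq_len(min(length(v), config$dfa_span_samples))]
}

#' Per-window feature extraction
#'
#' For one window: ADF test on the actual values, ACF features
#' (significant-lag count, peak count) on both the actual and first-order
#' differenced values, and the DFA scaling exponent on the undifferenced
#' post-event segment (DFA does not require stationarity, and differencing
#' would change the exponent by construction).
#'
#' @param window An [event_window()].
#' @param config A [pipeline_config()].
#' @param window_id Identifier recorded in the output row.
#' @return A tibble with one row per transform (`actual`, `differenced`):
#'   window metadata, ADF columns, ACF features, and `alpha` / `r_squared` /
#'   `n_scales` (on the `actual` row only).
#' @export
window_features <- function(window, config, window_id = "w1") {
  v <- window$values
  adf <- adf_test(v, alpha = config$alpha_level)
  dv <- difference(v)
  max_lag <- min(config$acf_max_lag, length(v) - 2L, length(dv) - 2L)
  fa <- acf_features(v, max_lag = max_lag, band = config$band,
                     peak_mode = config$peak_mode, transform = "actual")
  fd <- acf_features(dv, max_lag = max_lag, band = config$band,
                     peak_mode = config$peak_mode, transform = "differenced")
  dfa_v <- dfa_input(window, config)
  dfa <- dfa_alpha(dfa_v)
  meta <- tibble::tibble(
    participant_id = window$participant_id, window_id = window_id,
    label = window$label, center_time = window$center_time,
    coverage = window$coverage,
    adf_statistic = adf$statistic, adf_p = adf$p_value,
    stationary = isTRUE(adf$stationary)
  )
  dplyr::bind_cols(
    dplyr::bind_rows(meta, meta),
    dplyr::bind_rows(fa, fd),
    tibble::tibble(alpha = c(dfa$alpha, NA_real_),
                   r_squared = c(dfa$r_squared, NA_real_),
                   n_scales = c(length(dfa$scales), NA_integer_))
  )
}

#' Run the end-to-end analysis
#'
#' Simulate (or load) a cohort, filter artifacts, extract balanced stress
#' and normal windows, compute per-window ADF, ACF and DFA features, average
#' them per participant, and compare stress against normal with paired
#' t-tests. Participants with no retained stress window are excluded from
#' the comparison and listed in the manifest.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result`:
#'   * `report` — the comparison table (one row per metric x transform:
#'     group means, difference, paired t, p);
#'   * `summary` — the [summarize_cohort()] descriptives;
#'   * `features` — the per-window feature tibble;
#'   * `manifest` — config echo, seed, package version, per-stage counts.
#'   When `config$output_dir` is set, writes `features.csv`, `report.csv`,
#'   `report.json`, `summary.json`, `windows.csv` and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (!is.null(config$sim)) {
    simulate_cohort(config$sim)
  } else {
    read_cohort_csv(config$input_dir, age = config$age)
  }

  features <- list()
  all_stress_windows <- list()
  all_windows <- list()
  removed_fractions <- numeric(0)
  excluded <- character(0)
  participant_rows <- list()

  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    id <- p$series$participant_id
    filt <- filter_artifacts(p$series)
    removed_fractions[id] <- filt$removed_fraction
    sw <- extract_stress_windows(filt$series, p$events,
                                 half_width = config$half_width,
                                 min_coverage = config$min_coverage)
    nw <- sample_normal_windows(filt$series, p$events, n = length(sw),
                                half_width = config$half_width,
                                seed = derive_seed(config$seed, i),
                                min_coverage = config$min_coverage)
    if (!length(sw)) {
      excluded <- c(excluded, id)
      next
    }
    all_stress_windows <- c(all_stress_windows, sw)
    wins <- c(sw, nw)
    all_windows <- c(all_windows, wins)
    rows <- lapply(seq_along(wins), function(k) {
      window_features(wins[[k]], config,
                      window_id = sprintf("%s_%s_%03d", id,
                                          wins[[k]]$label, k))
    })
    participant_rows[[id]] <- dplyr::bind_rows(rows)
    features[[id]] <- participant_rows[[id]]
  }

  features <- dplyr::bind_rows(features)
  summary <- summarize_cohort(cohort, all_stress_windows)

  report <- NULL
  if (nrow(features)) {
    report <- build_report(features)
    if (is.null(report)) {
      warning("comparison skipped: fewer than 2 participants with both window types",
              call. = FALSE)
    }
  } else {
    warning("comparison skipped: no windows retained", call. = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("hrrhythm")),
    seed = config$seed,
    config = config_manifest(config),
    n_participants = length(cohort),
    n_stress_windows = if (nrow(features))
      sum(features$label == "stress" & features$transform == "actual") else 0L,
    n_normal_windows = if (nrow(features))
      sum(features$label == "normal" & features$transform == "actual") else 0L,
    removed_fraction = removed_fractions,
    excluded_participants = excluded
  )

  res <- structure(
    list(report = report, summary = summary, features = features,
         windows = all_windows, manifest = manifest),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) write_pipeline_outputs(res, config)
  res
}

# per-participant averaging then paired t per metric/transform
build_report <- function(features) {
  metrics <- list(
    list(parameter = "n_significant_lags", transform = "actual"),
    list(parameter = "n_significant_lags", transform = "differenced"),
    list(parameter = "n_peaks", transform = "actual"),
    list(parameter = "n_peaks", transform = "differenced"),
    list(parameter = "alpha", transform = "actual")
  )
  avg <- features |>
    dplyr::group_by(.data$participant_id, .data$label, .data$transform) |>
    dplyr::summarise(
      n_significant_lags = mean(.data$n_significant_lags),
      n_peaks = mean(.data$n_peaks),
      alpha = mean(.data$alpha),
      .groups = "drop"
    )
  rows <- lapply(metrics, function(m) {
    a <- avg[avg$transform == m$transform, ]
    wide <- merge(a[a$label == "stress", c("participant_id", m$parameter)],
                  a[a$label == "normal", c("participant_id", m$parameter)],
                  by = "participant_id", suffixes = c("_stress", "_normal"))
    wide <- wide[stats::complete.cases(wide), ]
    if (nrow(wide) < 2L) return(NULL)
    comparison_row(m$parameter, m$transform,
                   normal = wide[[paste0(m$parameter, "_normal")]],
                   stress = wide[[paste0(m$parameter, "_stress")]])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  dplyr::bind_rows(rows)
}

config_manifest <- function(config) {
  out <- unclass(config)
  out$output_dir <- NULL
  if (!is.null(out$sim)) {
    out$sim <- unclass(out$sim)
    out$sim$start_time <- format(out$sim$start_time, "%Y-%m-%dT%H:%M:%SZ",
                                 tz = "UTC")
  }
  out
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$output_dir, f)
  utils::write.csv(format_num_df(res$features), path("features.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(format_num_df(windows_to_table(res$windows)),
                   path("windows.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(res$report)) {
    utils::write.csv(format_num_df(res$report), path("report.csv"),
                     row.names = FALSE, quote = FALSE)
    jsonlite::write_json(res$report, path("report.json"), auto_unbox = TRUE,
                         digits = 10, pretty = TRUE)
  }
  jsonlite::write_json(unclass(res$summary), path("summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(res$manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(NULL)
}

# fixed-precision numeric formatting so reruns are byte-identical
format_num_df <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.8g", df[[nm]])
  }
  df
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$summary)
  if (!is.null(x$report)) {
    cat(sprintf("  comparison over %d participant pairs:\n",
                x$report$n_pairs[1L]))
    print(as.data.frame(x$report), digits = 4)
  } else {
    cat("  (no comparison report)\n")
  }
  invisible(x)
}
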