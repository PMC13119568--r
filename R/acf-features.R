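#' Autocorrelation function of a window
#'
#' Standard biased ACF estimator (lag-k cross-products normalised by the
#' series length and overall variance), computed via [stats::acf()], together
#' with a symmetric 95% significance band. Two band types are available:
#' the constant white-noise band `1.96/sqrt(n)` (default) and Bartlett's
#' cumulative large-lag band, which widens with the estimated low-lag
#' correlations.
#'
#' @param values Numeric window, length > `max_lag + 1`, non-zero variance.
#' @param max_lag Largest lag to compute (default: half the window length).
#' @param band `"white"` (constant `1.96/sqrt(n)`) or `"bartlett"`.
#' @param conf_level Confidence level of the band (default 0.95).
#' @return An object of class `acf_result`: `lags` (0..max_lag),
#'   `acf_values`, `conf_bound` (one threshold per lag), `n_effective`,
#'   `band`.
#' @export
#' @examples
#' set.seed(1)
#' a <- autocorrelation(rnorm(300), max_lag = 50)
#' count_significant_lags(a)
autocorrelation <- function(values, max_lag = NULL,
                            band = c("white", "bartlett"),
                            conf_level = 0.95) {
  band <- match.arg(band)
  assert_numeric_vector(values, "values", min_len = 4L)
  n <- length(values)
  if (is.null(max_lag)) max_lag <- n %/% 2L
  max_lag <- as.integer(max_lag)
  if (n <= max_lag + 1L) {
    stop("window length must exceed max_lag + 1", call. = FALSE)
  }
  if (stats::var(values) == 0) {
    stop("zero-variance window: autocorrelation undefined", call. = FALSE)
  }
  r <- drop(stats::acf(values, lag.max = max_lag, plot = FALSE,
                       demean = TRUE, type = "correlation")$acf)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (band == "white") {
    bound <- rep(z / sqrt(n), max_lag + 1L)
  } else {
    # Bartlett large-lag variance: var(r_k) ~ (1 + 2 sum_{j<k} r_j^2) / n
    cum_r2 <- c(0, cumsum(r[-1L]^2))[seq_len(max_lag + 1L)]
    bound <- z * sqrt((1 + 2 * c(0, cum_r2[-(max_lag + 1L)])) / n)
  }
  structure(
    list(lags = 0:max_lag, acf_values = r, conf_bound = bound,
         n_effective = n, band = band),
    class = "acf_result"
  )
}

#' Number of significant autocorrelation lags
#'
#' Counts the lags `k >= 1` whose autocorrelation exceeds the 95% band in
#' absolute value. Elevated counts indicate persistent serial structure.
#'
#' @param acf An `acf_result`.
#' @return Integer count, at most `max_lag`.
#' @export
count_significant_lags <- function(acf) {
  stopifnot(inherits(acf, "acf_result"))
  k <- seq_along(acf$lags)[-1L]
  sum(abs(acf$acf_values[k]) > acf$conf_bound[k])
}

#' Number of peaks in the autocorrelation sequence
#'
#' A peak is a strict interior local maximum of the ACF sequence over lags
#' `0..max_lag`: `acf[k-1] < acf[k] > acf[k+1]`. Ties break toward non-peak.
#' Rougher (less predictable) signals produce more peaks. With
#' `mode = "significant"` only peaks at lags exceeding the 95% band are
#' counted.
#'
#' @param acf An `acf_result` with `max_lag >= 2`.
#' @param mode `"all"` (default) or `"significant"`.
#' @return Integer count, at most `max_lag - 1`.
#' @export
count_peaks <- function(acf, mode = c("all", "significant")) {
  stopifnot(inherits(acf, "acf_result"))
  mode <- match.arg(mode)
  r <- acf$acf_values
  m <- length(r)
  if (m < 3L) stop("need max_lag >= 2 to count peaks", call. = FALSE)
  k <- 2:(m - 1L)
  is_peak <- r[k] > r[k - 1L] & r[k] > r[k + 1L]
  if (mode == "significant") {
    is_peak <- is_peak & abs(r[k]) > acf$conf_bound[k]
  }
  sum(is_peak)
}

#' Extract both ACF features from a window
#'
#' Convenience wrapper returning the significant-lag count and peak count for
#' one window and transform.
#'
#' @param values Numeric window.
#' @param max_lag Largest lag (default half the window length).
#' @param band Significance band type, see [autocorrelation()].
#' @param peak_mode Peak counting mode, see [count_peaks()].
#' @param transform Label recorded alongside the features
#'   (`"actual"` or `"differenced"`).
#' @return A tibble row: `transform`, `n_significant_lags`, `n_peaks`.
#' @export
acf_features <- function(values, max_lag = NULL, band = "white",
                         peak_mode = "all",
                         transform = c("actual", "differenced")) {
  transform <- match.arg(transform)
  a <- autocorrelation(values, max_lag = max_lag, band = band)
  tibble::tibble(
    transform = transform,
    n_significant_lags = count_significant_lags(a),
    n_peaks = count_peaks(a, mode = peak_mode)
  )
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("<acf_result> %d lags, n = %d, %s band; %d significant lags\n",
              max(x$lags), x$n_effective, x$band, count_significant_lags(x)))
  invisible(x)
}

#' Autocorrelation plot with significance band
#'
#' @param x An `acf_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.acf_result <- function(x, ...) {
  graphics::plot(x$lags, x$acf_values, type = "h", ylim = c(-1, 1),
                 xlab = "lag (samples)", ylab = "autocorrelation", ...)
  graphics::polygon(c(x$lags, rev(x$lags)),
                    c(x$conf_bound, rev(-x$conf_bound)),
                    col = grDevices::adjustcolor("lightblue", 0.5), border = NA)
  graphics::abline(h = 0)
}
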