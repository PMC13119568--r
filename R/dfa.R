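#' Detrended fluctuation analysis
#'
#' From-scratch DFA quantifying long-range correlation in a heart-rate (or
#' any) series. The series is integrated into a profile (cumulative sum of
#' deviations from the mean), split into equal-length segments, locally
#' detrended with a least-squares polynomial, and the pooled root-mean-square
#' fluctuation F(s) is measured across segment sizes s. The slope of
#' log10 F(s) versus log10 s is the scaling exponent alpha: about 0.5 for
#' white noise, 1.0 for pink (1/f) noise, 1.5 for Brownian motion.
#'
#' @name dfa
NULL

#' Integrated profile of a series
#'
#' `y[k] = sum_{i<=k} (x[i] - mean(x))`. The profile's last element is zero
#' up to rounding (the deviations telescope).
#'
#' @param values Numeric vector, length >= 16.
#' @return Numeric vector, same length as `values`.
#' @export
#' @examples
#' integrate_profile(c(rep(1, 8), rep(3, 8)))
integrate_profile <- function(values) {
  assert_numeric_vector(values, "values", min_len = 16L)
  cumsum(values - mean(values))
}

#' Root-mean-square fluctuation of a profile at one segment size
#'
#' The profile is cut into `floor(n/scale)` non-overlapping segments from the
#' start and the same number from the end, so the remainder at either end is
#' covered (standard both-ends segmentation). Each segment is detrended by a
#' least-squares polynomial of order `detrend_order`; the RMS of the pooled
#' residuals over all 2m segments is returned.
#'
#' @param profile Numeric vector (an integrated profile).
#' @param scale Segment length in samples; must satisfy
#'   `4 <= scale <= length(profile) / 4`.
#' @param detrend_order Polynomial order of the local detrend (default 1,
#'   linear).
#' @return A single non-negative number, the RMS fluctuation F(scale).
#' @export
fluctuation_at_scale <- function(profile, scale, detrend_order = 1) {
  assert_numeric_vector(profile, "profile", min_len = 16L)
  n <- length(profile)
  scale <- as.integer(scale)
  if (scale < 4L || scale > n %/% 4L) {
    stop(sprintf("`scale` must be in [4, %d] for a profile of length %d",
                 n %/% 4L, n), call. = FALSE)
  }
  if (detrend_order < 0 || detrend_order >= scale) {
    stop("`detrend_order` must be >= 0 and smaller than `scale`", call. = FALSE)
  }
  m <- n %/% scale
  fwd <- matrix(profile[seq_len(m * scale)], nrow = scale)
  bwd <- matrix(profile[seq.int(n - m * scale + 1L, n)], nrow = scale)
  seg <- cbind(fwd, bwd)
  # per-segment polynomial fit, shared design matrix across segments
  X <- outer(seq_len(scale), 0:detrend_order, `^`)
  coef <- solve(crossprod(X), crossprod(X, seg))
  resid <- seg - X %*% coef
  sqrt(mean(resid^2))
}

#' Default DFA segment sizes
#'
#' Approximately `n_scales` log-spaced integers spanning `[min_scale,
#' floor(n/4)]`, deduplicated after rounding.
#'
#' @param n Series length.
#' @param n_scales Number of scales requested before deduplication
#'   (default 15).
#' @param min_scale Smallest segment size (default 4).
#' @return Integer vector of segment sizes, strictly increasing.
#' @export
dfa_scales <- function(n, n_scales = 15, min_scale = 4) {
  max_scale <- n %/% 4L
  if (max_scale < min_scale) {
    stop("series too short: need length >= 4 * min_scale", call. = FALSE)
  }
  s <- exp(seq(log(min_scale), log(max_scale), length.out = n_scales))
  sort(unique(as.integer(round(s))))
}

#' DFA scaling exponent
#'
#' Runs the full DFA: profile integration, per-scale detrended fluctuations,
#' and an ordinary-least-squares fit of `log10 F` on `log10 scale`. The
#' fitted slope is the scaling exponent alpha.
#'
#' @param values Numeric series, length >= 16.
#' @param scales Integer vector of segment sizes (default
#'   `dfa_scales(length(values))`). At least 4 scales spanning a factor of 4
#'   are required.
#' @param detrend_order Local polynomial detrend order (default 1).
#' @return An object of class `dfa_result`: a list with `scales`,
#'   `fluctuations`, `alpha`, `fit_intercept`, `r_squared`, `n`.
#'   Scales whose fluctuation is zero or non-finite (e.g. an exactly linear
#'   profile) are dropped with a warning.
#' @export
#' @examples
#' set.seed(1)
#' dfa_alpha(rnorm(4096))$alpha  # white noise, about 0.5
dfa_alpha <- function(values, scales = NULL, detrend_order = 1) {
  assert_numeric_vector(values, "values", min_len = 16L)
  if (is.null(scales)) scales <- dfa_scales(length(values))
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 4L || max(scales) < 4 * min(scales)) {
    stop("need at least 4 scales spanning a factor of 4", call. = FALSE)
  }
  prof <- integrate_profile(values)
  f <- vapply(scales, function(s) fluctuation_at_scale(prof, s, detrend_order),
              numeric(1))
  keep <- is.finite(f) & f > 0
  if (!all(keep)) {
    warning(sprintf("dropping %d scale(s) with zero or non-finite fluctuation",
                    sum(!keep)), call. = FALSE)
    scales <- scales[keep]
    f <- f[keep]
  }
  if (length(scales) < 4L) {
    stop("fewer than 4 usable scales after dropping degenerate fluctuations",
         call. = FALSE)
  }
  lx <- log10(scales)
  ly <- log10(f)
  fit <- stats::lm.fit(cbind(1, lx), ly)
  alpha <- unname(fit$coefficients[2L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(
    list(scales = scales, fluctuations = f, alpha = alpha,
         fit_intercept = unname(fit$coefficients[1L]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n = length(values)),
    class = "dfa_result"
  )
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha = %.3f (R^2 = %.3f), %d scales [%d..%d], n = %d\n",
              x$alpha, x$r_squared, length(x$scales), min(x$scales),
              max(x$scales), x$n))
  invisible(x)
}

#' Log-log DFA plot
#'
#' Fluctuation versus segment size on log10 axes with the fitted scaling
#' line overlaid.
#'
#' @param x A `dfa_result`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dfa_result <- function(x, ...) {
  graphics::plot(log10(x$scales), log10(x$fluctuations),
                 xlab = "log10 segment size (samples)",
                 ylab = "log10 RMS fluctuation", pch = 19, ...)
  graphics::abline(x$fit_intercept, x$alpha, col = "grey40")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("alpha = %.3f", x$alpha))
}
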