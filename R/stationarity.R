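#' Augmented Dickey-Fuller unit-root test
#'
#' Tests each heart-rate window for stationarity before the autocorrelation
#' analysis. The ADF regression includes a constant and no trend term
#' (heart-rate windows have a nonzero mean but no prescribed deterministic
#' trend):
#'
#' `diff(y)[t] = c + gamma * y[t-1] + sum_i phi_i * diff(y)[t-i] + e[t]`
#'
#' The test statistic is `gamma / se(gamma)`; the p-value comes from the
#' MacKinnon approximate regression surface for the constant-only case. The
#' augmentation lag is chosen by AIC over `0..max_lag`, where `max_lag`
#' defaults to the Schwert rule `floor(12 * (n/100)^(1/4))`; candidate
#' models are compared on a common sample (trimmed by `max_lag`) and the
#' selected lag is then refit on the longest sample it allows.
#'
#' @param values Numeric sequence, length >= 20 after lag trimming.
#' @param max_lag Largest augmentation lag considered; default Schwert rule.
#' @param lag_policy `"aic"` (default: AIC selection up to `max_lag`) or
#'   `"fixed"` (use `max_lag` itself).
#' @param alpha Significance level for the `stationary` flag (default 0.05).
#' @return An object of class `adf_result`: `statistic`, `p_value`,
#'   `lags_used`, `stationary` (`p_value < alpha`), `n_obs`, `degenerate`.
#'   A constant series admits no unit-root regression and is returned with
#'   `degenerate = TRUE` and `NA` statistic/p-value.
#' @export
#' @examples
#' set.seed(1)
#' adf_test(rnorm(200))            # stationary: p near 0
#' adf_test(cumsum(rnorm(200)))    # random walk: large p
adf_test <- function(values, max_lag = NULL,
                     lag_policy = c("aic", "fixed"), alpha = 0.05) {
  lag_policy <- match.arg(lag_policy)
  assert_numeric_vector(values, "values", min_len = 20L)
  y <- as.double(values)
  n <- length(y)
  if (stats::sd(y) == 0) {
    return(structure(
      list(statistic = NA_real_, p_value = NA_real_, lags_used = NA_integer_,
           stationary = NA, n_obs = n, degenerate = TRUE),
      class = "adf_result"
    ))
  }
  if (is.null(max_lag)) {
    max_lag <- floor(12 * (n / 100)^0.25)
    max_lag <- min(max_lag, (n - 1) %/% 2 - 2)
  }
  max_lag <- as.integer(max(0L, max_lag))
  dy <- diff(y)
  if (length(dy) - max_lag < 20L) {
    stop("series too short for the requested lag order", call. = FALSE)
  }

  if (lag_policy == "fixed") {
    k <- max_lag
  } else {
    # AIC over a common sample trimmed by max_lag
    aics <- vapply(0:max_lag, function(k) {
      fit <- adf_ols(y, dy, k, trim = max_lag)
      nobs <- fit$nobs
      # Gaussian OLS log-likelihood AIC
      ll <- -nobs / 2 * (log(2 * pi) + log(fit$rss / nobs) + 1)
      -2 * ll + 2 * (k + 2)
    }, numeric(1))
    k <- which.min(aics) - 1L
  }
  fit <- adf_ols(y, dy, k, trim = k)
  stat <- fit$gamma / fit$se_gamma
  p <- mackinnon_p(stat)
  structure(
    list(statistic = stat, p_value = p, lags_used = k,
         stationary = p < alpha, n_obs = fit$nobs, degenerate = FALSE),
    class = "adf_result"
  )
}

# ADF OLS regression of dy[t] on (1, y[t-1], dy[t-1..t-k]), sample trimmed
# by `trim` >= k so candidate lag orders share observations.
adf_ols <- function(y, dy, k, trim) {
  n_dy <- length(dy)
  idx <- (trim + 1L):n_dy             # response indices into dy
  resp <- dy[idx]
  X <- cbind(1, y[idx])               # y[t-1]: dy[t] = y[t+1]-y[t] at idx t
  if (k > 0L) {
    for (i in seq_len(k)) X <- cbind(X, dy[idx - i])
  }
  qr_fit <- stats::lm.fit(X, resp)
  res <- qr_fit$residuals
  nobs <- length(resp)
  rss <- sum(res^2)
  df <- nobs - ncol(X)
  sigma2 <- rss / df
  piv <- qr_fit$qr$pivot
  XtXinv <- chol2inv(qr.R(qr_fit$qr))[order(piv), order(piv), drop = FALSE]
  list(gamma = unname(qr_fit$coefficients[2L]),
       se_gamma = sqrt(sigma2 * XtXinv[2L, 2L]),
       rss = rss, nobs = nobs)
}

# MacKinnon (1994/2010) approximate asymptotic p-value surface for the
# ADF tau statistic, constant-only regression, single series.
mackinnon_p <- function(stat) {
  tau_star <- -1.61
  tau_min <- -18.83
  tau_max <- 2.74
  if (!is.finite(stat)) return(NA_real_)
  if (stat > tau_max) return(1)
  if (stat < tau_min) return(0)
  if (stat <= tau_star) {
    co <- c(2.1659, 1.4412, 0.038269)            # small-p polynomial
  } else {
    co <- c(1.7339, 0.93202, -0.12745, -0.010368) # large-p polynomial
  }
  stats::pnorm(sum(co * stat^(seq_along(co) - 1)))
}

#' @export
print.adf_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<adf_result> degenerate: constant series, no unit-root regression\n")
  } else {
    cat(sprintf("<adf_result> tau = %.4f, p = %.4g, lags = %d, %s (n = %d)\n",
                x$statistic, x$p_value, x$lags_used,
                if (x$stationary) "stationary" else "non-stationary", x$n_obs))
  }
  invisible(x)
}

#' First-order (or higher) differencing
#'
#' `difference(x)[i] = x[i+1] - x[i]`, applied `order` times. Used to render
#' non-stationary windows stationary before the autocorrelation analysis;
#' following the study design it is applied to every window uniformly, with
#' per-window ADF results recorded for reporting only.
#'
#' @param values Numeric sequence with `length > order`.
#' @param order Differencing order (default 1).
#' @return Numeric vector of length `length(values) - order`.
#' @export
#' @examples
#' difference(c(1, 3, 6))  # c(2, 3)
difference <- function(values, order = 1) {
  order <- as.integer(order)
  if (order < 1L) stop("`order` must be >= 1", call. = FALSE)
  assert_numeric_vector(values, "values", min_len = 2L)
  if (length(values) <= order) {
    stop("`values` must be longer than the differencing order", call. = FALSE)
  }
  diff(values, differences = order)
}
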