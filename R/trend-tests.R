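#' Mann-Kendall trend test
#'
#' Nonparametric test for a monotonic trend in an ordered sequence, with no
#' normality assumption. The statistic is `S = sum_{i<j} sign(x[j] - x[i])`;
#' its variance uses the standard correction for tied groups, and the normal
#' approximation applies a continuity correction of one unit toward zero.
#'
#' @param values Ordered numeric sequence, length >= 4.
#' @param alpha Significance level used to label the `direction`
#'   (default 0.05).
#' @return An object of class `mk_result`: `statistic` (S), `var_s`, `z`,
#'   `p_value` (two-sided), `direction` (`"increasing"`, `"decreasing"` or
#'   `"none"`), `n`, `degenerate`. An all-tied sequence is degenerate:
#'   S = 0, variance 0, p reported as 1.
#' @export
#' @examples
#' mann_kendall(c(1, 3, 2, 4, 6, 5, 7, 9, 8, 10))
mann_kendall <- function(values, alpha = 0.05) {
  assert_numeric_vector(values, "values", min_len = 4L)
  n <- length(values)
  s <- sum(sign(outer(values, values, `-`))[lower.tri(matrix(0, n, n))])
  ties <- table(values)
  ties <- ties[ties > 1L]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  degenerate <- var_s <= 0
  if (degenerate) {
    z <- 0
    p <- 1
  } else {
    z <- if (s > 0) (s - 1) / sqrt(var_s) else if (s < 0) (s + 1) / sqrt(var_s) else 0
    p <- 2 * stats::pnorm(-abs(z))
  }
  direction <- if (!degenerate && p < alpha) {
    if (s > 0) "increasing" else "decreasing"
  } else "none"
  structure(
    list(statistic = s, var_s = var_s, z = z, p_value = p,
         direction = direction, n = n, degenerate = degenerate),
    class = "mk_result"
  )
}

#' @export
print.mk_result <- function(x, ...) {
  cat(sprintf("<mk_result> S = %.0f, z = %.3f, p = %.4g, direction: %s (n = %d)\n",
              x$statistic, x$z, x$p_value, x$direction, x$n))
  invisible(x)
}

#' Paired t-test between two related samples
#'
#' Student's t on the elementwise differences `d = a - b`:
#' `t = mean(d) / (sd(d)/sqrt(n))` with `n - 1` degrees of freedom
#' (computed via [stats::t.test()]). In the stress-versus-normal comparison
#' `a` holds the per-participant stress averages and `b` the normal
#' averages, so a positive t means stress > normal.
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @param alternative Two-sided by default; `"greater"`/`"less"` available.
#' @return An object of class `paired_t_result`: `t_statistic`, `p_value`,
#'   `df`, `n_pairs`, `mean_a`, `mean_b`, `mean_diff`, `degenerate`.
#'   Zero-variance differences (e.g. `a` identical to `b`) are flagged
#'   degenerate with no p-value.
#' @export
paired_t <- function(a, b, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  assert_numeric_vector(a, "a", min_len = 2L)
  assert_numeric_vector(b, "b", min_len = 2L)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  d <- a - b
  if (stats::var(d) == 0) {
    return(structure(
      list(t_statistic = NA_real_, p_value = NA_real_, df = length(d) - 1L,
           n_pairs = length(d), mean_a = mean(a), mean_b = mean(b),
           mean_diff = mean(d), degenerate = TRUE),
      class = "paired_t_result"
    ))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
  structure(
    list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
         df = unname(tt$parameter), n_pairs = length(d),
         mean_a = mean(a), mean_b = mean(b), mean_diff = mean(d),
         degenerate = FALSE),
    class = "paired_t_result"
  )
}

#' @export
print.paired_t_result <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<paired_t_result> degenerate (zero-variance differences), n = %d\n",
                x$n_pairs))
  } else {
    cat(sprintf("<paired_t_result> t = %.4f, df = %.0f, p = %.4g, mean diff = %.4g\n",
                x$t_statistic, x$df, x$p_value, x$mean_diff))
  }
  invisible(x)
}

#' One comparison-report row
#'
#' Builds a row of the stress-versus-normal comparison table from the
#' per-participant averages of one extracted metric: group means, their
#' difference (stress minus normal), and the paired t-test.
#'
#' @param parameter Metric label (e.g. `"n_significant_lags"`).
#' @param transform `"actual"` or `"differenced"`.
#' @param normal,stress Numeric vectors of per-participant averages, paired
#'   by position.
#' @return A one-row tibble: `parameter`, `transform`, `mean_normal`,
#'   `mean_stress`, `difference`, `t_statistic`, `p_value`, `n_pairs`.
#' @export
comparison_row <- function(parameter, transform, normal, stress) {
  pt <- paired_t(stress, normal)
  tibble::tibble(
    parameter = parameter, transform = transform,
    mean_normal = mean(normal), mean_stress = mean(stress),
    difference = mean(stress) - mean(normal),
    t_statistic = pt$t_statistic, p_value = pt$p_value,
    n_pairs = pt$n_pairs
  )
}
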