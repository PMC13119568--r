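# Independent brute-force reference implementations used to validate the
# package's vectorised code paths. These deliberately favour clarity over
# speed and share no code with R/.

# DFA by explicit per-segment loops with lm() detrending
naive_dfa <- function(values, scales, detrend_order = 1) {
  prof <- cumsum(values - mean(values))
  n <- length(prof)
  f <- sapply(scales, function(s) {
    m <- n %/% s
    sq <- c()
    for (dir in c("fwd", "bwd")) {
      for (v in seq_len(m)) {
        idx <- if (dir == "fwd") ((v - 1) * s + 1):(v * s)
               else (n - v * s + 1):(n - (v - 1) * s)
        seg <- prof[idx]
        x <- seq_len(s)
        fit <- stats::lm(seg ~ poly(x, detrend_order, raw = TRUE))
        sq <- c(sq, stats::residuals(fit)^2)
      }
    }
    sqrt(mean(sq))
  })
  lx <- log10(scales)
  ly <- log10(f)
  list(fluctuations = f,
       alpha = unname(stats::coef(stats::lm(ly ~ lx))[2]))
}

# biased ACF estimator by explicit double loop
naive_acf <- function(x, max_lag) {
  n <- length(x)
  xb <- mean(x)
  denom <- sum((x - xb)^2)
  sapply(0:max_lag, function(k) {
    num <- 0
    for (t in 1:(n - k)) num <- num + (x[t] - xb) * (x[t + k] - xb)
    num / denom
  })
}

# Mann-Kendall S by exhaustive pair enumeration
naive_mk_s <- function(x) {
  n <- length(x)
  s <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) s <- s + sign(x[j] - x[i])
  }
  s
}

# all permutations of a vector (small n only)
all_permutations <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# quick synthetic window helper: AR(1) signal around a mean
ar1_window <- function(n, phi, seed, mean = 80, sd = 5) {
  set.seed(seed)
  as.numeric(mean + sd * arima.sim(list(ar = phi), n))
}
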