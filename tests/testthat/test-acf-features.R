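test_that("ACF estimator matches the brute-force double loop to 1e-10", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- 75 + 5 * as.numeric(arima.sim(list(ar = 0.6), 200))
    a <- autocorrelation(x, max_lag = 40)
    expect_equal(a$acf_values, naive_acf(x, 40), tolerance = 1e-10)
    expect_equal(a$acf_values[1], 1)
    expect_true(all(abs(a$acf_values) <= 1 + 1e-12))
  }
})

test_that("AR(1) autocorrelation approaches phi^k", {
  x <- ar1_window(20000, phi = 0.5, seed = 1)
  a <- autocorrelation(x, max_lag = 5)
  expect_equal(a$acf_values[-1], 0.5^(1:5), tolerance = 0.05)
})

test_that("white-noise series exceed the 95% band at about the nominal rate", {
  props <- vapply(1:50, function(seed) {
    set.seed(seed)
    a <- autocorrelation(rnorm(1200), max_lag = 300)
    count_significant_lags(a) / 300
  }, numeric(1))
  expect_gt(mean(props), 0.03)
  expect_lt(mean(props), 0.08)
})

test_that("significant-lag count increases with persistence", {
  strong <- weak <- numeric(20)
  for (i in 1:20) {
    strong[i] <- count_significant_lags(
      autocorrelation(ar1_window(1200, 0.9, seed = i), max_lag = 600))
    weak[i] <- count_significant_lags(
      autocorrelation(ar1_window(1200, 0.2, seed = 1000 + i), max_lag = 600))
  }
  expect_gt(mean(strong), mean(weak))
})

test_that("peak counting follows the strict-local-maximum definition", {
  a <- structure(
    list(lags = 0:5, acf_values = c(1, 0.2, 0.5, 0.1, 0.4, 0.0),
         conf_bound = rep(0.3, 6), n_effective = 100, band = "white"),
    class = "acf_result"
  )
  expect_identical(count_peaks(a), 2L)
  expect_identical(count_peaks(a, mode = "significant"), 2L)
  # drop the 0.4 peak below the band
  a$conf_bound <- rep(0.45, 6)
  expect_identical(count_peaks(a, mode = "significant"), 1L)

  # monotone decay has no interior maxima; ties break toward non-peak
  dec <- autocorrelation(ar1_window(5000, 0.9, seed = 3), max_lag = 4)
  expect_true(all(diff(dec$acf_values) < 0))
  expect_identical(count_peaks(dec), 0L)
  flat <- structure(
    list(lags = 0:3, acf_values = c(1, 0.4, 0.4, 0.1),
         conf_bound = rep(0.2, 4), n_effective = 100, band = "white"),
    class = "acf_result"
  )
  expect_identical(count_peaks(flat), 0L)
})

test_that("ACF features are invariant to adding a constant", {
  x <- ar1_window(400, 0.5, seed = 7)
  f1 <- acf_features(x, max_lag = 100)
  f2 <- acf_features(x + 250, max_lag = 100)
  expect_identical(f1$n_significant_lags, f2$n_significant_lags)
  expect_identical(f1$n_peaks, f2$n_peaks)
})

test_that("rough signals have more ACF peaks than persistent ones", {
  rough <- smooth <- numeric(20)
  for (i in 1:20) {
    set.seed(i)
    rough[i] <- count_peaks(autocorrelation(rnorm(1200), max_lag = 600))
    smooth[i] <- count_peaks(
      autocorrelation(ar1_window(1200, 0.95, seed = 500 + i), max_lag = 600))
  }
  expect_gt(mean(rough), mean(smooth))
})

test_that("degenerate and invalid ACF inputs are rejected", {
  expect_error(autocorrelation(rep(70, 100), max_lag = 10), "variance")
  expect_error(autocorrelation(rnorm(20), max_lag = 30), "max_lag")
})

test_that("Bartlett band is wider than the white-noise band beyond lag 1", {
  x <- ar1_window(1200, 0.8, seed = 9)
  w <- autocorrelation(x, max_lag = 50, band = "white")
  b <- autocorrelation(x, max_lag = 50, band = "bartlett")
  expect_true(all(b$conf_bound[-(1:2)] > w$conf_bound[-(1:2)]))
  expect_lte(count_significant_lags(b), count_significant_lags(w))
})
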