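test_that("slopes are exact on a noise-free geometric sequence", {
  x <- 64 * 0.5^(0:10) # a_{t+1} = 0.5 a_t exactly
  sl <- regression_slopes(x, k_max = 3, dt = 4)
  expect_equal(sl$slopes[1], 0.5, tolerance = 1e-12)
  expect_equal(sl$slopes[2], 0.25, tolerance = 1e-12)
  expect_equal(sl$n_pairs, c(10L, 9L, 8L))
})

test_that("slopes match an independently coded OLS fit (lm oracle)", {
  set.seed(42)
  x <- as.numeric(arima.sim(list(ar = 0.7), 500) + 10)
  sl <- regression_slopes(x, k_max = 5, dt = 4)
  for (k in 1:5) {
    fit <- lm(x[(k + 1):500] ~ x[1:(500 - k)])
    expect_equal(sl$slopes[k], unname(coef(fit)[2]), tolerance = 1e-12)
  }
})

test_that("iid counts give near-zero slopes; degenerate input errors", {
  set.seed(1)
  a <- binned_activity(rpois(5e4, 5), dt = 4)
  sl <- regression_slopes(a, k_max = 10)
  expect_true(all(abs(sl$slopes) < 0.02))
  expect_error(regression_slopes(rep(3, 100), k_max = 5, dt = 4),
               "zero variance")
})

test_that("exponential fit recovers noiseless geometric slopes exactly", {
  k <- 1:150
  for (m_true in c(0.5, 0.9, 0.98)) {
    for (b_true in c(0.08, 0.5, 1)) {
      sl <- structure(list(lags = k, slopes = b_true * m_true^k,
                           n_pairs = rep(1000L, length(k)), dt = 4),
                      class = "regression_slopes")
      f <- fit_exponential(sl)
      expect_lt(abs(f$m_hat - m_true), 1e-10)
      expect_lt(abs(f$b_hat - b_true), 1e-10)
    }
  }
})

test_that("tau_hat satisfies the algebraic identity -dt/ln(m_hat)", {
  run <- quick_net(m = 0.98, L = 2e5, seed = 21)
  est <- mr_estimate(run$sampled_counts, k_max = 150)
  expect_equal(est$tau_hat, -4 / log(est$m_hat), tolerance = 1e-12)
})

test_that("MR is subsampling-invariant while the lag-1 estimator is biased", {
  run <- quick_net(m = 0.98, L = 5e5, n = 50, seed = 8, raster = TRUE)
  est_full <- mr_estimate(run$sampled_counts, k_max = 150)
  expect_equal(est_full$m_hat, 0.98, tolerance = 0.01)
  # conventional estimator collapses under subsampling (0.21-like bias)
  conv <- conventional_estimate(run$sampled_counts)
  expect_lt(conv, 0.3)
  expect_lt(conv, est_full$m_hat)
  # b_hat is far below 1 under strong subsampling, near 1 at full sampling
  expect_lt(est_full$b_hat, 0.5)
  est_net <- mr_estimate(run$full_counts, k_max = 150)
  expect_equal(est_net$b_hat, 1, tolerance = 0.1)
  expect_equal(conventional_estimate(run$full_counts), 0.98,
               tolerance = 0.01)
})

test_that("b_hat shrinks and m_hat stays flat as subsets shrink (medians)", {
  run <- quick_net(m = 0.9, L = 3e5, n = 60, seed = 12, raster = TRUE)
  med <- function(np, what) {
    ests <- vapply(1:8, function(i) {
      a <- subsample(run, np, seed = 100 * np + i)
      mr_estimate(a, k_max = 80)[[what]]
    }, 0)
    median(ests)
  }
  bs <- vapply(c(10, 30, 60), med, 0, what = "b_hat")
  ms <- vapply(c(10, 30, 60), med, 0, what = "m_hat")
  expect_true(all(diff(bs) > 0))
  expect_true(all(abs(ms - 0.9) < 0.02))
})

test_that("windowing arithmetic and stationarity null behave", {
  # 295 s at 4 ms = 73750 bins -> exactly 59 windows of 5 s
  run <- quick_net(m = 0.98, L = 73750, seed = 31)
  w <- window_estimates(run$sampled_counts, window = 5, k_max = 150)
  expect_identical(w$n_windows, 59L)
  expect_length(w$window_m, 59L)
  expect_true(is.na(w$passed))
  # against its own matched model the Levene test is non-significant
  matched <- branching_params(m = 0.98, rate = 7.25, N = 1e4, n = 50,
                              L = 73750L, seed = 77)
  w2 <- window_estimates(run$sampled_counts, window = 5, k_max = 150,
                         matched = matched, seed = 5)
  expect_gt(w2$variability_p, 0.05)
  expect_error(window_estimates(run$sampled_counts, window = 0.2),
               "100 bins")
})

test_that("consistency battery passes a stationary trace, flags violations", {
  run <- quick_net(m = 0.9, L = 73750, seed = 41)
  ct <- consistency_tests(run$sampled_counts, k_max = 100, seed = 2)
  expect_true(ct$fit_adequacy)
  expect_true(ct$trend)
  expect_true(ct$passed)

  # linear rate ramp (rate doubles): trend flag must fire
  fx <- make_fixture("ramp", seed = 3, duration_s = 150)
  ct_ramp <- consistency_tests(bin_spikes(fx$raster, 4), k_max = 100,
                               seed = 2)
  expect_false(ct_ramp$trend)
  expect_false(ct_ramp$passed)

  # power-law slope decay: fit-adequacy flag must fire
  k <- 1:100
  sl <- structure(list(lags = k, slopes = 0.5 * k^(-0.7),
                       n_pairs = rep(1000L, 100), dt = 4),
                  class = "regression_slopes")
  ad <- fit_adequacy(sl)
  expect_false(ad$pass)
  expect_identical(ad$best, "powerlaw")
  # while genuinely geometric slopes pass
  sl$slopes <- 0.3 * 0.95^k
  expect_true(fit_adequacy(sl)$pass)
})

test_that("step-change trace is flagged by the window panel", {
  fx <- make_fixture("step_change", seed = 9, duration_s = 150)
  act <- bin_spikes(fx$raster, 4)
  matched <- branching_params(m = 0.98, rate = 7.25, N = 1e4, n = 50,
                              L = length(act$counts), seed = 13)
  w <- window_estimates(act, window = 5, k_max = 100, matched = matched,
                        seed = 3)
  ct <- consistency_tests(act, k_max = 100, seed = 3)
  # either the variance comparison or the rate trend must reject
  expect_true(isFALSE(w$passed) || isFALSE(ct$trend))
})

test_that("confidence intervals cover the truth on a matched run", {
  p <- branching_params(m = 0.9, rate = 7.25, N = 1e4, n = 50, L = 5e4,
                        seed = 3)
  run <- simulate_network(p, raster = FALSE)
  est <- mr_estimate(run$sampled_counts, k_max = 100)
  # matched model built from the estimate, as in real use
  rate <- mean(run$sampled_counts$counts) / 50 / 0.004
  pm <- branching_params(m = est$m_hat, rate = rate, N = 1e4, n = 50,
                         L = 5e4, seed = 3)
  est <- confidence_interval(est, pm, B = 30, seed = 17)
  expect_lt(est$ci$m_5_95[1], 0.9)
  expect_gt(est$ci$m_5_95[2], 0.9)
  expect_lt(est$ci$m_16_84[1], est$ci$m_16_84[2])
  expect_equal(est$ci$n_failed, 0L)
})

test_that("subsampling invariance curve is flat for the model", {
  run <- quick_net(m = 0.9, L = 5e5, n = 50, seed = 19, raster = TRUE)
  curve <- subsampling_invariance_curve(run, c(10, 25, 50), repeats = 10,
                                        k_max = 80, seed = 4)
  expect_true(all(abs(curve$median_m - 0.9) < 0.02))
  expect_lt(diff(range(curve$median_m)), 0.02)
})
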