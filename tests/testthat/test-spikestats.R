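test_that("ISI statistics: regular train, Poisson train, exclusions", {
  # clock-like unit: ISIs all equal, CV = 0
  reg <- spike_raster(rep(1L, 4), c(0, 10, 20, 30) / 1000, t_end = 0.04)
  s <- isi_statistics(reg)
  expect_equal(unname(s$isi[["1"]]), rep(0.010, 3), tolerance = 1e-9)
  expect_equal(unname(s$cv[["1"]]), 0)

  # homogeneous Poisson unit: exponential ISIs, CV -> 1, mean 1/lambda
  set.seed(2)
  t_p <- cumsum(rexp(4000, rate = 5))
  pois <- spike_raster(rep(1L, 4000), t_p)
  sp <- isi_statistics(pois)
  expect_equal(mean(sp$isi[["1"]]), 1 / 5, tolerance = 0.05)
  expect_equal(unname(sp$cv[["1"]]), 1, tolerance = 0.06)

  # units with < 2 spikes are excluded and reported
  mix <- spike_raster(c(1L, 1L, 2L), c(0.1, 0.2, 0.15), t_end = 0.3)
  sm <- isi_statistics(mix)
  expect_identical(sm$excluded, 2L)
})

test_that("Fano factor is 1 for Poisson activity at every bin size", {
  set.seed(3)
  a <- binned_activity(rpois(4e5, 2), dt = 4)
  fc <- fano_factor(a, c(4, 40, 400, 4000), scope = "population")
  # sampling error of a variance ratio over n windows: sd ~ sqrt(2/n)
  n_win <- 4e5 / (fc$bin_size / 4)
  expect_true(all(abs(fc$fano - 1) < pmax(4 * sqrt(2 / n_win), 0.02)))
})

test_that("single-unit CV and Fano near 1 for AI and reverberating models", {
  for (m in c(0, 0.98)) {
    run <- quick_net(m = m, L = 73750, n = 50, seed = 5 + m * 100,
                     raster = TRUE)
    s <- isi_statistics(run$sampled_raster)
    expect_gt(median(s$cv, na.rm = TRUE), 0.9)
    expect_lt(median(s$cv, na.rm = TRUE), 1.1)
    fc <- fano_factor(run$sampled_raster, c(4, 40), scope = "single_unit")
    expect_gt(fc$fano[1], 0.9); expect_lt(fc$fano[1], 1.1)
  }
})

test_that("full-network Fano dwarfs single-unit Fano and grows with bin size", {
  run <- quick_net(m = 0.98, L = 2e5, n = 50, seed = 23, raster = TRUE)
  f_net <- fano_factor(run$full_counts, c(4, 400, 4000),
                       scope = "full_network")
  expect_gt(f_net$fano[1], 10)            # far above 1 already at 4 ms
  expect_true(all(diff(f_net$fano) > 0))  # grows by orders of magnitude
  f_su <- fano_factor(run$sampled_raster, c(4, 4000), scope = "single_unit")
  expect_lt(f_su$fano[2], f_net$fano[3])
})

test_that("activity distribution normalizes and matches Poisson at m = 0", {
  A <- quick_pop(m = 0, h = 2, L = 5e4)
  pd <- activity_distribution(A, 4)
  expect_equal(sum(pd$p), 1, tolerance = 1e-12)
  expect_equal(pd$p[pd$count <= 6],
               dpois(0:6, 2), tolerance = 0.05)
  expect_error(activity_distribution(A, 6), "multiple")
})

test_that("reverberating activity has a heavier tail than AI at matched mean", {
  ai <- quick_net(m = 0, L = 1e5, seed = 1)$sampled_counts
  rev <- quick_net(m = 0.98, L = 1e5, seed = 1)$sampled_counts
  q99 <- quantile(ai$counts, 0.99)
  expect_gt(mean(rev$counts > q99), mean(ai$counts > q99))
})

test_that("avalanche detection matches the run-length definition", {
  a <- binned_activity(c(0, 2, 3, 0, 0, 1, 0), dt = 4)
  av <- detect_avalanches(a)
  expect_equal(av$sizes, c(5, 1))
  expect_equal(av$durations, c(2, 1))
  # all-zero trace -> empty set; no-gap trace flagged
  expect_equal(detect_avalanches(binned_activity(rep(0, 10), 4))$n_avalanches, 0L)
  expect_true(detect_avalanches(binned_activity(c(1, 2, 1), 4))$single_run)
})

test_that("avalanche invariants hold on random traces (conservation)", {
  set.seed(7)
  for (i in 1:20) {
    x <- rpois(500, runif(1, 0.2, 3))
    av <- detect_avalanches(binned_activity(x, 4))
    expect_equal(sum(av$sizes), sum(x))
    if (av$n_avalanches > 0) {
      expect_true(all(av$sizes >= av$durations))
      expect_true(all(av$durations >= 1))
    }
  }
})

test_that("near-critical avalanches are heavy-tailed, AI avalanches are not", {
  nc <- quick_net(m = 0.9999, L = 2e5, seed = 3)$sampled_counts
  ai <- quick_net(m = 0, L = 2e5, seed = 3)$sampled_counts
  av_nc <- detect_avalanches(nc); av_ai <- detect_avalanches(ai)
  expect_gt(max(av_nc$sizes), 20 * max(av_ai$sizes))
})

test_that("avalanche likelihood: self-match is maximal, cross-match ranks truth", {
  rev <- quick_net(m = 0.98, L = 2e5, seed = 13)$sampled_counts
  ai <- quick_net(m = 0, L = 2e5, seed = 14)$sampled_counts
  nc <- quick_net(m = 0.9999, L = 2e5, seed = 15)$sampled_counts
  cands <- list(AI = ai, reverberating = rev, near_critical = nc)
  # data = candidate trace itself -> that candidate wins
  lik_self <- avalanche_model_likelihood(detect_avalanches(rev), cands)
  expect_identical(lik_self$model[1], "reverberating")
  lik_ai <- avalanche_model_likelihood(detect_avalanches(ai), cands)
  expect_identical(lik_ai$model[1], "AI")
  # fresh data from the reverberating model -> reverberating wins
  rev2 <- quick_net(m = 0.98, L = 73750, seed = 99)$sampled_counts
  lik2 <- avalanche_model_likelihood(detect_avalanches(rev2), cands)
  expect_identical(lik2$model[1], "reverberating")
})

test_that("spike-count correlations: independent units ~0, model grows with bin size", {
  set.seed(11)
  # 20 independent Poisson units
  un <- rep(1:20, each = 400)
  tm <- as.vector(replicate(20, sort(runif(400, 0, 100))))
  ras <- spike_raster(un, tm, t_end = 100)
  cc <- spike_count_correlation(ras, c(4, 400))
  expect_true(all(abs(cc$mean_rsc) < 0.02))
  expect_equal(cc$n_pairs[1], 190)

  run <- quick_net(m = 0.98, L = 73750, n = 50, seed = 44, raster = TRUE)
  cm <- spike_count_correlation(run$sampled_raster, c(4, 40, 400, 2000))
  expect_true(all(diff(cm$mean_rsc) > 0)) # non-decreasing with bin size
  expect_lt(cm$mean_rsc[1], 0.05)         # tiny at 4 ms
  expect_gt(cm$mean_rsc[4], 0.1)          # large at 2 s

  # shuffling spike times destroys correlations
  set.seed(12)
  shuf <- spike_raster(run$sampled_raster$unit,
                       runif(length(run$sampled_raster$time), 0,
                             run$sampled_raster$t_end),
                       t_end = run$sampled_raster$t_end)
  cs <- spike_count_correlation(shuf, c(4, 400))
  expect_true(all(abs(cs$mean_rsc) < 0.02))
})

test_that("autocorrelation recovers tau on population activity", {
  for (m in c(0.9, 0.98)) {
    A <- quick_pop(m = m, h = 290 * (1 - m), L = 5e5, seed = 29)
    ac <- autocorrelation(A, max_lag = 150)
    expect_equal(ac$tau_ms, -4 / log(m), tolerance = 0.1)
    expect_equal(ac$values[1], 1)
  }
})

test_that("single-unit autocorrelation shows the subsampling drop", {
  run <- quick_net(m = 0.98, L = 2e5, n = 50, seed = 31, raster = TRUE)
  one <- subsample(run, 1, seed = 8)
  ac <- autocorrelation(one, max_lag = 150)
  # sharp drop from r0 = 1 to a low floor
  expect_equal(ac$values[1], 1)
  expect_lt(ac$values[2], 0.05)
  # the floor still decays with the network timescale (within 25%)
  expect_equal(ac$tau_ms, -4 / log(0.98), tolerance = 0.25)
  # a naive fit including lag 0 returns a drastically smaller timescale
  expect_lt(ac$tau_naive_ms, ac$tau_ms / 4)
})
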