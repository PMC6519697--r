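test_that("pure-immigration population run is Poisson with mean h", {
  A <- quick_pop(m = 0, h = 290, L = 2e4)
  x <- A$counts
  expect_equal(mean(x), 290, tolerance = 3 * sqrt(290 / length(x)) / 290)
  # Poisson signature: variance/mean near 1
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
  # and essentially no lag-1 correlation
  expect_lt(abs(conventional_estimate(A)), 0.02)
})

test_that("long-run mean matches h/(1-m) within 3 standard errors", {
  for (m in c(0, 0.9, 0.98)) {
    h <- 290 * (1 - m)
    A <- quick_pop(m = m, h = h, L = 2e5, seed = 7)
    x <- A$counts
    # SE of the mean of an AR(1)-like chain: inflate iid SE by (1+m)/(1-m)
    se <- sd(x) / sqrt(length(x)) * sqrt((1 + m) / (1 - m))
    expect_lt(abs(mean(x) - 290), 3 * se + 1e-9)
  }
})

test_that("fully sampled lag-1 slope equals m (autocovariance oracle)", {
  for (m in c(0.9, 0.98)) {
    A <- quick_pop(m = m, h = 290 * (1 - m), L = 5e5, seed = 3)
    expect_equal(conventional_estimate(A), m, tolerance = 0.01)
  }
})

test_that("poisson offspring option behaves like the binomial default", {
  A <- quick_pop(m = 0.9, h = 29, L = 2e5, seed = 5, offspring = "poisson")
  expect_equal(mean(A$counts), 290, tolerance = 0.02)
  expect_equal(conventional_estimate(A), 0.9, tolerance = 0.01)
})

test_that("simulation is deterministic given the seed", {
  p <- branching_params(m = 0.9, h = 29, N = 1e4, n = 30, L = 5e3, seed = 99)
  A1 <- simulate_population(p); A2 <- simulate_population(p)
  expect_identical(A1$counts, A2$counts)
  r1 <- simulate_network(p, raster = TRUE)
  r2 <- simulate_network(p, raster = TRUE)
  expect_identical(r1$full_counts$counts, r2$full_counts$counts)
  expect_identical(r1$sampled_raster$unit, r2$sampled_raster$unit)
  expect_identical(r1$sampled_raster$time, r2$sampled_raster$time)
})

test_that("stationary simulation rejects m >= 1 and the cap triggers", {
  p <- branching_params(m = 1, h = 1, L = 100, seed = 1)
  expect_error(simulate_population(p), "m >= 1")
  expect_error(simulate_network(p), "m >= 1")
  p2 <- branching_params(m = 3, h = 0, L = 500, kappa = 4, seed = 2)
  expect_error(simulate_population(p2, stationary = FALSE, A0 = 10,
                                   cap = 1e4),
               "cap")
})

test_that("supercritical growth averages factor m per bin", {
  p <- branching_params(m = 2, h = 0, L = 8, kappa = 4, seed = 1)
  g <- replicate(300, {
    p$seed <- sample.int(1e6, 1)
    A <- simulate_population(p, stationary = FALSE, A0 = 100L)
    mean(A$counts[-1] / pmax(A$counts[-length(A$counts)], 1))
  })
  expect_equal(mean(g), 2, tolerance = 0.05)
})

test_that("network and population simulators agree in mean and slope", {
  # Collisions between external and recurrent activations (each neuron
  # counts once per bin) give the network an effective branching ratio
  # m_eff = m * (1 - h/N), hence mean h/(1 - m_eff): a ~2-3% finite-size
  # correction at these rates.
  m <- 0.9; h <- 29; N <- 1e4
  m_eff <- m * (1 - h / N)
  Ap <- quick_pop(m = m, h = h, L = 2e5, seed = 11)
  run <- quick_net(m = m, L = 2e5, seed = 11)
  expect_equal(mean(run$full_counts$counts), h / (1 - m_eff),
               tolerance = 0.01)
  expect_equal(mean(Ap$counts), h / (1 - m), tolerance = 0.01)
  expect_equal(conventional_estimate(run$full_counts), m_eff,
               tolerance = 0.01)
  expect_equal(conventional_estimate(Ap), m, tolerance = 0.01)
})

test_that("network run obeys count invariants and per-unit rates", {
  run <- quick_net(m = 0.98, L = 5e4, n = 50, seed = 2, raster = TRUE)
  a <- run$sampled_counts$counts; A <- run$full_counts$counts
  expect_true(all(a <= A))
  expect_true(all(a <= 50))
  # per-unit rate approx 7.25 Hz: <a_t>/(n*dt)
  rate <- mean(a) / 50 / 0.004
  expect_equal(rate, 7.25, tolerance = 0.05)
  # raster re-bins exactly to the sampled counts
  expect_identical(bin_spikes(run$sampled_raster, 4)$counts, a)
})

test_that("subsample returns identity, 0/1 counts, and preserves rate", {
  run <- quick_net(m = 0.9, L = 2e4, n = 40, seed = 6, raster = TRUE)
  full <- subsample(run, 40)
  expect_identical(full$counts, run$sampled_counts$counts)
  one <- subsample(run, 1, seed = 3)
  expect_true(all(one$counts %in% c(0L, 1L)))
  expect_error(subsample(run, 41), "between 1 and")
  # per-unit rate independent of subset size
  rates <- vapply(c(5, 10, 20, 40), function(np)
    mean(subsample(run, np, seed = np)$counts) / np, 0)
  expect_lt(diff(range(rates)) / mean(rates), 0.15)
})
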