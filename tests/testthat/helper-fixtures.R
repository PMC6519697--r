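# Small, fast simulation settings shared across tests.  Heavier runs used
# by individual tests are built inline so their cost is visible there.

quick_net <- function(m = 0.98, L = 5e4, n = 50, seed = 1L, N = 1e4,
                      rate = 7.25, raster = FALSE) {
  p <- branching_params(m = m, rate = rate, N = N, n = n, L = L, seed = seed)
  simulate_network(p, raster = raster)
}

quick_pop <- function(m, h, L = 1e5, seed = 1L, ...) {
  p <- branching_params(m = m, h = h, N = 1e4, L = L, seed = seed)
  simulate_population(p, ...)
}

# independent pure-R Galton-Watson total-progeny oracle (binomial offspring)
gw_total_progeny <- function(m, kappa = 4, trials = 1000) {
  vapply(seq_len(trials), function(i) {
    d <- 1; tot <- 1
    while (d > 0) {
      d <- rbinom(1, kappa * d, m / kappa)
      tot <- tot + d
    }
    tot
  }, 0)
}
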