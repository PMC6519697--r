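#' Parameter set for a branching-network simulation
#'
#' Bundles everything needed to reproduce one run of the branching model
#' with immigration: the branching ratio `m` (mean number of spikes
#' directly triggered by one spike), the mean total external input `h`
#' (spikes per bin across the whole network), the network size `N`, the
#' number of sampled units `n`, the out-degree `kappa`, the bin width
#' `dt`, the run length `L` in bins, and the RNG seed.
#'
#' The model is stationary only for `m < 1`; constructors therefore allow
#' any `m >= 0` but stationary simulation entry points reject `m >= 1`.
#' The per-connection activation probability `p = m/kappa` must lie in
#' \[0, 1\].
#'
#' @param m branching ratio (dimensionless, >= 0).
#' @param h mean total external input per bin (spikes/bin, >= 0).  Give
#'   either `h` or `rate`.
#' @param rate per-neuron firing rate in Hz; when given, `h` is derived
#'   with [solve_input_rate()] so that the stationary rate matches.
#' @param N network size (number of neurons).
#' @param n number of sampled units, `1 <= n <= N`.
#' @param kappa out-degree of each neuron (default 4).
#' @param dt bin width in milliseconds (default 4).
#' @param L run length in bins.
#' @param seed RNG seed (integer).
#' @return An object of class `branching_params`.
#' @examples
#' branching_params(m = 0.98, rate = 7.25, N = 1e4, n = 50, L = 1e5, seed = 1)
#' @export
branching_params <- function(m, h = NULL, rate = NULL, N = 10000L, n = N,
                             kappa = 4, dt = 4, L = 100000L, seed = 1L) {
    stopifnot(is.numeric(m), length(m) == 1L, m >= 0, is.finite(m))
    if (is.null(h) && is.null(rate))
        stop("give either 'h' or 'rate'")
    if (!is.null(h) && !is.null(rate))
        stop("give only one of 'h' and 'rate'")
    if (is.null(h))
        h <- solve_input_rate(rate, dt = dt, N = N, m = m)
    stopifnot(h >= 0, N >= 1, n >= 1, n <= N, kappa >= 1, kappa <= N - 1,
              dt > 0, L >= 1)
    p <- m / kappa
    if (p < 0 || p > 1)
        stop("per-connection probability p = m/kappa = ", signif(p, 4),
             " outside [0, 1]")
    structure(list(m = m, h = h, N = as.integer(N), n = as.integer(n),
                   kappa = kappa, dt = dt, L = as.integer(L),
                   seed = as.integer(seed)),
              class = "branching_params")
}

#' @export
print.branching_params <- function(x, ...) {
    cat("Branching-network parameters\n")
    cat(sprintf("  m = %g, h = %g spikes/bin, N = %d, n = %d, kappa = %g\n",
                x$m, x$h, x$N, x$n, x$kappa))
    cat(sprintf("  dt = %g ms, L = %d bins, seed = %d\n", x$dt, x$L, x$seed))
    if (x$m < 1 && x$m > 0)
        cat(sprintf("  tau = %.1f ms, <A> = %.2f spikes/bin\n",
                    tau_from_m(x$m, x$dt), x$h / (1 - x$m)))
    invisible(x)
}

#' External input rate matching a target firing rate
#'
#' For a stationary branching network with branching ratio `m`, the mean
#' activity is `<A> = h/(1-m)`.  Matching a per-neuron firing rate `R`
#' (so that `<A> = R * dt * N`) therefore requires total external input
#' `h = R * dt * N * (1 - m)` spikes per bin, with `dt` in seconds.
#'
#' @param rate target per-neuron firing rate in Hz.
#' @param dt bin width in milliseconds.
#' @param N network size.
#' @param m branching ratio, `0 <= m < 1`.
#' @return External input `h` in spikes per bin (total over the network).
#' @examples
#' solve_input_rate(7.25, dt = 4, N = 1e4, m = 0.98) # 5.8
#' @export
solve_input_rate <- function(rate, dt, N, m) {
    stopifnot(rate > 0, dt > 0, N >= 1, m >= 0)
    if (m >= 1)
        stop("no stationary rate match exists for m >= 1")
    rate * (dt / 1000) * N * (1 - m)
}

#' Stationary mean activity of the branching model
#'
#' Closed form `<A> = h/(1-m)` implied by stationarity of the update
#' `A_{t+1} = sum_i Y_{t,i} + h_t`.
#'
#' @param params a [branching_params()] object, or a branching ratio `m`
#'   when `h` is given.
#' @param h external input (spikes/bin); only when `params` is numeric.
#' @return Mean activity in spikes per bin.
#' @export
stationary_mean <- function(params, h = NULL) {
    if (inherits(params, "branching_params")) {
        m <- params$m; h <- params$h
    } else {
        m <- params
        stopifnot(is.numeric(h))
    }
    if (m >= 1)
        stop("stationary mean undefined for m >= 1")
    h / (1 - m)
}

#' Convert between branching ratio and intrinsic network timescale
#'
#' The population autocorrelation of a stationary branching network
#' decays exponentially, `r(dt*k) = b * m^k = b * exp(-k*dt/tau)`, so the
#' intrinsic network timescale is `tau = -dt/ln(m)` and conversely
#' `m = exp(-dt/tau)`.  `tau` is independent of the bin width; `m` must
#' always be interpreted together with `dt`.
#'
#' @param m branching ratio in (0, 1).
#' @param tau intrinsic timescale in milliseconds (> 0).
#' @param dt bin width in milliseconds.
#' @return `tau_from_m`: timescale in ms; `m_from_tau`: branching ratio.
#' @examples
#' tau_from_m(0.98, 4)   # about 198 ms
#' m_from_tau(12, 4)     # about 0.72
#' @export
tau_from_m <- function(m, dt) {
    stopifnot(dt > 0)
    ifelse(m <= 0, 0, ifelse(m >= 1, Inf, -dt / log(m)))
}

#' @rdname tau_from_m
#' @export
m_from_tau <- function(tau, dt) {
    stopifnot(dt > 0, tau > 0)
    exp(-dt / tau)
}
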