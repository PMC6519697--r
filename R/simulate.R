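#' Simulate the branching process with immigration at population level
#'
#' Iterates the population update `A_{t+1} = sum_{i=1}^{A_t} Y_{t,i} + h_t`
#' where each spike triggers on average `m` offspring and the immigration
#' `h_t` is Poisson with mean `h` per bin.  The default offspring law is
#' Binomial(`kappa * A_t`, `m/kappa`) in total, matching the per-connection
#' Bernoulli trials of the network mapping; `offspring = "poisson"` draws
#' Poisson(`m * A_t`) instead.
#'
#' For a stationary run (`stationary = TRUE`, requires `m < 1`) the chain
#' starts at `A_0 = round(h/(1-m))` and a burn-in of `ceiling(10 * tau/dt)`
#' bins is simulated and discarded, removing initialization transients that
#' would otherwise bias slope estimates.  With `stationary = FALSE` the
#' chain starts at `A0` and nothing is discarded (use this for avalanche
#' or supercritical experiments, any `m >= 0`).
#'
#' @param params a [branching_params()] object.
#' @param stationary logical; see Details.
#' @param offspring `"binomial"` (default) or `"poisson"`.
#' @param A0 initial activity for non-stationary runs (default 0).
#' @param cap explosion guard: an error identifying the bin is raised if
#'   activity exceeds `cap`.  Default `100 * max(<A>, 1)` for stationary
#'   runs, `Inf` otherwise.
#' @param return_input if `TRUE`, the realized immigration sequence `h_t`
#'   is attached as attribute `"input"`.
#' @return A [binned_activity()] with `label = "full"` of length `params$L`.
#' @examples
#' p <- branching_params(m = 0.9, h = 29, N = 1e4, L = 1e4, seed = 42)
#' A <- simulate_population(p)
#' mean(A$counts) # close to 290
#' @export
simulate_population <- function(params, stationary = TRUE,
                                offspring = c("binomial", "poisson"),
                                A0 = 0L, cap = NULL, return_input = FALSE) {
    stopifnot(inherits(params, "branching_params"))
    offspring <- match.arg(offspring)
    m <- params$m; h <- params$h
    if (stationary) {
        if (m >= 1)
            stop("stationary run requested but m >= 1 (non-stationary regime)")
        A0 <- as.integer(round(h / (1 - m)))
        burn <- if (m > 0) as.integer(ceiling(-10 / log(m))) else 0L
        if (is.null(cap)) cap <- 100 * max(h / (1 - m), 1)
    } else {
        burn <- 0L
        if (is.null(cap)) cap <- Inf
    }
    set.seed(params$seed)
    A <- .sim_population_cpp(params$L + burn, m, h, params$kappa,
                             as.integer(A0), cap,
                             offspring == "poisson", return_input)
    inp <- attr(A, "input")
    if (burn > 0L) {
        A <- A[-seq_len(burn)]
        if (!is.null(inp)) inp <- inp[-seq_len(burn)]
    }
    out <- binned_activity(A, dt = params$dt, label = "full",
                           n_units = params$N)
    if (return_input) attr(out, "input") <- inp
    out
}

#' Simulate the branching model on an annealed-disorder random network
#'
#' Maps the branching process onto a network of `N` neurons: each active
#' neuron activates each of its `kappa` postsynaptic targets with
#' probability `p = m/kappa`, targets are drawn without replacement across
#' all sources (a neuron is counted active at most once per bin), and
#' external input arrives as independent Poisson activation of each neuron
#' at rate `h/N` per bin.  Connectivity is redrawn every step (annealed
#' disorder), so neurons are statistically interchangeable; the simulator
#' exploits this to run at the count level and assigns sampled-unit
#' identities afterwards (an exact reformulation).
#'
#' A fixed set of `n` units is sampled once before the run; their per-bin
#' spiking is returned both as summed counts `a_t` and, optionally, as a
#' spike raster (spike times placed uniformly within their bin).
#'
#' @inheritParams simulate_population
#' @param raster if `TRUE` (default) a [spike_raster()] of the sampled
#'   units is generated; disable for long runs where only the counts are
#'   needed.
#' @return An object of class `network_run` with elements `full_counts`
#'   (the activity `A_t`), `sampled_counts` (`a_t` of the `n` sampled
#'   units), `sampled_raster` (or `NULL`), and `params`.  If the total
#'   requested activations ever exceeded `N` the run carries
#'   `saturated = TRUE` and a warning is issued.
#' @examples
#' p <- branching_params(m = 0.98, rate = 7.25, N = 1e4, n = 50,
#'                       L = 2e4, seed = 7)
#' run <- simulate_network(p, raster = FALSE)
#' mean(run$sampled_counts$counts) # about 1.45 spikes/bin
#' @export
simulate_network <- function(params, stationary = TRUE, A0 = 0L,
                             raster = TRUE) {
    stopifnot(inherits(params, "branching_params"))
    m <- params$m; h <- params$h; N <- params$N; n <- params$n
    if (stationary) {
        if (m >= 1)
            stop("stationary run requested but m >= 1 (non-stationary regime)")
        A0 <- as.integer(round(h / (1 - m)))
        burn <- if (m > 0) as.integer(ceiling(-10 / log(m))) else 0L
    } else {
        burn <- 0L
    }
    set.seed(params$seed)
    sim <- .sim_network_cpp(params$L + burn, m, h, N, n, params$kappa,
                            as.integer(A0))
    A <- sim$A; a <- sim$a
    if (burn > 0L) { A <- A[-seq_len(burn)]; a <- a[-seq_len(burn)] }
    if (isTRUE(sim$saturated))
        warning("requested activations exceeded N in at least one bin; ",
                "activity saturated at N (near-critical guard)")
    ras <- NULL
    if (raster) {
        asg <- .assign_units_cpp(a, n)
        dt_s <- params$dt / 1000
        times <- (asg$bin + stats::runif(length(asg$bin))) * dt_s
        t_end <- length(a) * dt_s
        if (length(times) == 0L)
            stop("no spikes among sampled units; cannot build raster")
        ras <- spike_raster(asg$unit, times, t_end = t_end, n_units = n)
    }
    structure(list(
        full_counts = binned_activity(A, dt = params$dt, label = "full",
                                      n_units = N),
        sampled_counts = binned_activity(a, dt = params$dt,
                                         label = "subsampled", n_units = n),
        sampled_raster = ras,
        saturated = isTRUE(sim$saturated),
        params = params), class = "network_run")
}

#' @export
print.network_run <- function(x, ...) {
    cat("Branching-network run\n  ")
    print(x$params)
    cat(sprintf("  <A_t> = %.2f, <a_t> = %.3f spikes/bin%s\n",
                mean(x$full_counts$counts), mean(x$sampled_counts$counts),
                if (x$saturated) " [saturated]" else ""))
    invisible(x)
}

#' Further subsample a network run
#'
#' Sums the per-bin spiking of a uniformly chosen fixed subset of
#' `n_prime` of the sampled units.  The subset is drawn once (before any
#' counting) and kept fixed, mirroring how electrode subsets would be
#' dropped from a recording.
#'
#' @param run a `network_run` with a raster, or a [spike_raster()].
#' @param n_prime number of units to keep.
#' @param seed optional seed for the subset draw.
#' @return A [binned_activity()] of the subset's summed counts (bin width
#'   taken from the run; for a raw raster supply `dt`).
#' @param dt bin width in ms (only needed when `run` is a raster).
#' @export
subsample <- function(run, n_prime, seed = NULL, dt = NULL) {
    if (inherits(run, "network_run")) {
        ras <- run$sampled_raster
        if (is.null(ras)) stop("run carries no raster; rerun with raster = TRUE")
        if (is.null(dt)) dt <- run$params$dt
    } else if (inherits(run, "spike_raster")) {
        ras <- run
        if (is.null(dt)) stop("supply dt when subsampling a raw raster")
    } else stop("run must be a network_run or spike_raster")
    units <- sort(unique(ras$unit))
    if (n_prime < 1 || n_prime > length(units))
        stop("n_prime must be between 1 and the ", length(units),
             " available units")
    if (!is.null(seed)) set.seed(seed)
    keep <- if (n_prime == length(units)) units else sample(units, n_prime)
    sel <- ras$unit %in% keep
    if (!any(sel)) {
        n_bins <- floor(ras$t_end / (dt / 1000) + 1e-9)
        return(binned_activity(integer(n_bins), dt = dt, n_units = n_prime))
    }
    sub <- spike_raster(ras$unit[sel], ras$time[sel], t_end = ras$t_end,
                        n_units = n_prime)
    out <- bin_spikes(sub, dt = dt)
    out$n_units <- as.integer(n_prime)
    attr(out, "units") <- keep
    out
}
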