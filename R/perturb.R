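#' Cascade of a single extra spike
#'
#' Simulates what happens after one additional spike is triggered on top
#' of ongoing activity.  Because the branching model is linear in its
#' input, the extra activity is exactly the descendant tree of the
#' trigger: a Galton-Watson chain with offspring Binomial(`kappa`,
#' `m/kappa`) per extra spike (protocol `"tree"`, the default and exact
#' route).  Protocol `"paired"` follows the literal experiment instead:
#' pairs of independent background runs with and without the injected
#' spike, whose rate difference averages to the same cascade but is far
#' noisier.
#'
#' Per trial the cascade contributes `Delta_t` extra spikes in bin `t`
#' (with `Delta_1 = 1`, the trigger), terminates after `d` bins for
#' `m < 1`, and accumulates `s = sum_t Delta_t` extra spikes in total.
#' The triggering spike is counted in `s` (so `s = 1` when `m = 0`);
#' subtract 1 for the "additional spikes only" convention.
#'
#' @param m branching ratio (>= 0; for `m >= 1` the cap is essential).
#' @param kappa out-degree (default 4).
#' @param trials number of cascades (default 500).
#' @param dt bin width in ms (labels the time axis only).
#' @param seed RNG seed.
#' @param protocol `"tree"` or `"paired"`.
#' @param max_spikes per-trial cap; trials reaching it are marked
#'   censored, never silently truncated (default 1e7).
#' @param t_keep number of leading bins over which the trial-averaged
#'   `Delta_t` profile is recorded (default 2000).
#' @param h,N,L background-run settings for the paired protocol.
#' @return An object of class `perturbation_ensemble`: `sizes`,
#'   `durations`, `censored`, `delta_rate` (trial-averaged extra spikes
#'   per bin), `m`, `dt`, `trials`, `protocol`.
#' @examples
#' pe <- perturbation_cascade(0.98, trials = 1000, seed = 1)
#' mean(pe$sizes) # near 1/(1-0.98) = 50
#' @export
perturbation_cascade <- function(m, kappa = 4, trials = 500, dt = 4,
                                 seed = 1L,
                                 protocol = c("tree", "paired"),
                                 max_spikes = 1e7, t_keep = 2000,
                                 h = 10, N = 10000L, L = 200L) {
    protocol <- match.arg(protocol)
    stopifnot(m >= 0, trials >= 1, m / kappa <= 1)
    set.seed(seed)
    if (protocol == "tree") {
        res <- .cascade_cpp(as.integer(trials), m, kappa, max_spikes,
                            as.integer(t_keep))
        out <- list(sizes = res$size, durations = res$duration,
                    censored = res$censored,
                    delta_rate = res$delta_sum / trials,
                    m = m, dt = dt, trials = trials, protocol = protocol)
    } else {
        if (m >= 1) stop("paired protocol requires a stationary background (m < 1)")
        base <- branching_params(m = m, h = h, N = N, L = as.integer(L),
                                 seed = seed)
        delta <- matrix(0, nrow = trials, ncol = L)
        A0 <- as.integer(round(h / (1 - m)))
        for (i in seq_len(trials)) {
            s1 <- .sim_population_cpp(L, m, h, kappa, A0 + 1L, Inf, FALSE,
                                      FALSE)
            s0 <- .sim_population_cpp(L, m, h, kappa, A0, Inf, FALSE, FALSE)
            delta[i, ] <- s1 - s0
        }
        dr <- colMeans(delta)
        out <- list(sizes = rowSums(delta) + 1, durations = rep(NA_real_,
                    trials), censored = rep(FALSE, trials),
                    delta_rate = c(1, dr), m = m, dt = dt, trials = trials,
                    protocol = protocol)
    }
    class(out) <- "perturbation_ensemble"
    out
}

#' @export
print.perturbation_ensemble <- function(x, ...) {
    cat(sprintf("Perturbation ensemble: %d trials at m = %g (%s protocol)\n",
                x$trials, x$m, x$protocol))
    cat(sprintf("  mean size %.2f, mean duration %.1f bins, %d censored\n",
                mean(x$sizes), mean(x$durations, na.rm = TRUE),
                sum(x$censored)))
    invisible(x)
}

#' Mean total perturbation size
#'
#' Expected total number of spikes descending from one extra spike
#' (trigger included): the Galton-Watson total progeny mean
#' `1/(1-m) = sum_g m^g`, which diverges at criticality.  Set
#' `include_trigger = FALSE` for the "additional spikes" reading
#' (`m/(1-m)`).
#'
#' @param m branching ratio, `m < 1`.
#' @param include_trigger count the triggering spike itself (default
#'   `TRUE`).
#' @return Expected perturbation size.
#' @export
mean_perturbation_size <- function(m, include_trigger = TRUE) {
    stopifnot(m >= 0)
    if (any(m >= 1)) stop("mean perturbation size diverges for m >= 1")
    if (include_trigger) 1 / (1 - m) else m / (1 - m)
}

#' Susceptibility of the stationary rate to external input
#'
#' `chi = dR/dh = 1/(1-m)`: one extra input spike per bin raises the
#' stationary activity by `1/(1-m)` spikes per bin.  Diverges at the
#' critical point; equals 1 for a purely input-driven network.
#'
#' @param m branching ratio, `m < 1`.
#' @return Susceptibility (dimensionless).
#' @export
susceptibility <- function(m) {
    stopifnot(m >= 0)
    if (any(m >= 1)) stop("susceptibility diverges for m >= 1")
    1 / (1 - m)
}

#' Fraction of activity generated by external input
#'
#' In the stationary state `<A> = h/(1-m)`, so the externally generated
#' fraction of all spikes is `h/<A> = 1 - m`; the remaining `m` is
#' recurrent activation.  Optionally cross-checked by counting
#' input-attributed spikes in a simulated run.
#'
#' @param m branching ratio in `[0, 1]`.
#' @param simulate if `TRUE`, also simulate a population run and report
#'   the empirical input fraction alongside the closed form.
#' @param params simulation settings (a [branching_params()]) for the
#'   cross-check; required when `simulate = TRUE`.
#' @return The fraction `1 - m`, or when `simulate = TRUE` a list
#'   `closed_form`, `simulated`.
#' @export
external_fraction <- function(m, simulate = FALSE, params = NULL) {
    stopifnot(m >= 0, m <= 1)
    if (!simulate) return(1 - m)
    stopifnot(inherits(params, "branching_params"))
    A <- simulate_population(params, return_input = TRUE)
    list(closed_form = 1 - m,
         simulated = sum(attr(A, "input")) / sum(A$counts))
}

#' Summary of the dynamical state implied by a branching ratio
#'
#' Bundles the closed-form predictions that follow from `m` alone: the
#' intrinsic timescale `tau = -dt/ln(m)`, the susceptibility
#' `chi = 1/(1-m)`, the external-input fraction `1-m`, and the mean
#' perturbation size `1/(1-m)`.  These satisfy
#' `chi = mean size = 1/external fraction` exactly.
#'
#' @param m branching ratio, `0 <= m < 1` (for `m >= 1` divergent fields
#'   are `Inf` and flagged).
#' @param dt bin width in ms.
#' @return An object of class `state_summary`.
#' @examples
#' state_summary(0.98, 4) # tau ~ 198 ms, chi = 50, external 2%
#' @export
state_summary <- function(m, dt = 4) {
    stopifnot(m >= 0, dt > 0)
    div <- m >= 1
    structure(list(
        m = m, dt = dt,
        tau_ms = tau_from_m(m, dt),
        susceptibility = if (div) Inf else 1 / (1 - m),
        external_fraction = max(1 - m, 0),
        mean_perturbation_size = if (div) Inf else 1 / (1 - m),
        divergent = div), class = "state_summary")
}

#' @export
print.state_summary <- function(x, ...) {
    cat(sprintf("Dynamical state at m = %g (dt = %g ms)\n", x$m, x$dt))
    cat(sprintf("  intrinsic timescale tau  : %.1f ms\n", x$tau_ms))
    cat(sprintf("  susceptibility chi       : %g\n", x$susceptibility))
    cat(sprintf("  external-input fraction  : %.3g%%\n",
                100 * x$external_fraction))
    cat(sprintf("  mean perturbation size   : %g spikes\n",
                x$mean_perturbation_size))
    if (x$divergent) cat("  [m >= 1: divergent quantities flagged]\n")
    invisible(x)
}
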