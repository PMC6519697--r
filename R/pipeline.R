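#' Build the three matched surrogate models for a recording
#'
#' Given a recording (raster or binned counts) and an estimated branching
#' ratio, constructs parameter sets for the asynchronous-irregular
#' (`m = 0`), reverberating (`m = m_hat`), and near-critical
#' (`m = 0.9999` by default) branching networks, all matched to the
#' recording in the number of sampled units `n` and per-unit firing rate
#' `R = <a_t>/(n * dt)`, via `h = R * dt * N * (1 - m)`.  The three specs
#' share `N`, `n`, `dt`, and target rate; they differ only in `(m, h)`.
#'
#' @param recording a [spike_raster()] or [binned_activity()].
#' @param m_hat estimated branching ratio of the recording (in (0, 1);
#'   values outside are clipped into (0, 1) with a flag).
#' @param N full network size for the surrogates (default 1e4).
#' @param dt bin width in ms.
#' @param m_near branching ratio of the near-critical surrogate.
#' @param L run length in bins for each surrogate (default 1e5).
#' @param seed base seed; surrogate i uses `seed + i`.
#' @return A named list of class `matched_models` with elements `AI`,
#'   `reverberating`, `near_critical` (each a [branching_params()]),
#'   plus `rate`, `n`, and `clipped`.
#' @examples
#' # the worked example of the cat recording: m = 0.98, n = 50, R = 7.25 Hz
#' a <- binned_activity(rep(1:2, 500), dt = 4, n_units = 50)
#' @export
match_models <- function(recording, m_hat, N = 10000L, dt = 4,
                         m_near = 0.9999, L = 100000L, seed = 1L) {
    if (inherits(recording, "spike_raster")) {
        act <- bin_spikes(recording, dt = dt)
    } else if (inherits(recording, "binned_activity")) {
        act <- recording; dt <- act$dt
    } else stop("recording must be a spike_raster or binned_activity")
    n <- act$n_units
    if (is.na(n)) stop("recording does not carry its number of units")
    rate <- mean(act$counts) / n / (dt / 1000)
    clipped <- FALSE
    if (!is.finite(m_hat) || m_hat <= 0 || m_hat >= 1) {
        m_hat <- min(max(m_hat, 1e-4), 1 - 1e-4)
        clipped <- TRUE
        warning("m_hat outside (0,1); reverberating surrogate clipped to ",
                signif(m_hat, 4))
    }
    mk <- function(m, i) branching_params(m = m, rate = rate, N = N, n = n,
                                          dt = dt, L = as.integer(L),
                                          seed = as.integer(seed + i))
    structure(list(AI = mk(0, 1L), reverberating = mk(m_hat, 2L),
                   near_critical = mk(m_near, 3L),
                   rate = rate, n = n, clipped = clipped),
              class = "matched_models")
}

#' @export
print.matched_models <- function(x, ...) {
    cat(sprintf("Matched surrogate models (n = %d, R = %.3f Hz)\n", x$n,
                x$rate))
    for (lbl in c("AI", "reverberating", "near_critical"))
        cat(sprintf("  %-14s m = %-7g h = %g spikes/bin\n", lbl,
                    x[[lbl]]$m, x[[lbl]]$h))
    invisible(x)
}

# Jensen-Shannon divergence between two count pmfs given as data.frames
# (count, p); supports are aligned by padding with zeros.
.js_divergence <- function(pa, pb) {
    M <- max(pa$count, pb$count)
    a <- b <- numeric(M + 1)
    a[pa$count + 1] <- pa$p; b[pb$count + 1] <- pb$p
    mm <- (a + b) / 2
    kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
    0.5 * kl(a, mm) + 0.5 * kl(b, mm)
}

#' Validate a recording against its matched surrogate models
#'
#' Simulates the three matched models, computes the validation panels for
#' recording and models (ISI coefficient of variation, Fano-factor
#' curve, activity distributions at 4 and 40 ms, avalanche size/duration
#' distributions with likelihood comparison, spike-count correlations,
#' and the population autocorrelation timescale), and assembles a report
#' with a per-panel closest-model verdict.  Scalar panels are compared by
#' absolute difference, activity distributions by Jensen-Shannon
#' divergence, and avalanches by model likelihood.  A failing panel is
#' isolated (recorded as an error message), not fatal.
#'
#' @param recording a [spike_raster()].
#' @param models a `matched_models` object from [match_models()].
#' @param run_length surrogate run length in bins; default
#'   `max(recording bins, 1e5)`.
#' @param seed base seed for the surrogate simulations.
#' @param fano_bins,rsc_bins bin sizes (ms) for the Fano and correlation
#'   panels.
#' @return A list of class `validation_report` with `recording`,
#'   `models` (per-model panel lists), `verdicts`, `likelihood`, and full
#'   provenance (`seeds`, `run_length`).
#' @export
validate_recording <- function(recording, models, run_length = NULL,
                               seed = 1L,
                               fano_bins = c(4, 40, 400, 4000),
                               rsc_bins = c(4, 40, 400, 2000)) {
    stopifnot(inherits(recording, "spike_raster"),
              inherits(models, "matched_models"))
    dt <- models$AI$dt
    rec_act <- bin_spikes(recording, dt = dt)
    if (is.null(run_length))
        run_length <- max(length(rec_act$counts), 100000L)

    panel <- function(raster, act) {
        out <- list()
        safe <- function(expr) tryCatch(expr, error = function(e)
            paste("panel failed:", conditionMessage(e)))
        out$cv_median <- safe(stats::median(isi_statistics(raster)$cv,
                                            na.rm = TRUE))
        out$fano <- safe(fano_factor(raster, fano_bins,
                                     scope = "single_unit", dt = dt))
        out$p_at_4 <- safe(activity_distribution(act, dt))
        out$p_at_40 <- safe(activity_distribution(act, 10 * dt))
        out$avalanches <- safe(detect_avalanches(act))
        out$rsc <- safe(spike_count_correlation(raster, rsc_bins, dt = dt))
        out$autocorr <- safe(autocorrelation(act,
                                             max_lag = min(150,
                                                 length(act$counts) %/% 3)))
        out
    }

    rec_panel <- panel(recording, rec_act)
    labels <- c("AI", "reverberating", "near_critical")
    runs <- list(); mod_panels <- list()
    for (i in seq_along(labels)) {
        p <- models[[labels[i]]]
        p$L <- as.integer(run_length)
        p$seed <- as.integer(seed + i)
        run <- simulate_network(p, raster = TRUE)
        runs[[labels[i]]] <- run
        mod_panels[[labels[i]]] <- panel(run$sampled_raster,
                                         run$sampled_counts)
    }

    lik <- tryCatch(
        avalanche_model_likelihood(rec_panel$avalanches,
            lapply(runs, function(r) r$sampled_counts)),
        error = function(e) NULL)

    verdict <- function(metric) {
        vals <- vapply(labels, function(l) {
            v <- mod_panels[[l]][[metric]]
            if (is.numeric(v) && length(v) == 1) v else NA_real_
        }, 0)
        ref <- rec_panel[[metric]]
        if (!is.numeric(ref) || any(!is.finite(vals))) return(NA_character_)
        labels[which.min(abs(vals - ref))]
    }
    verdicts <- list(cv = verdict("cv_median"))
    verdicts$activity_4ms <- tryCatch(
        labels[which.min(vapply(labels, function(l)
            .js_divergence(rec_panel$p_at_4, mod_panels[[l]]$p_at_4), 0))],
        error = function(e) NA_character_)
    verdicts$activity_40ms <- tryCatch(
        labels[which.min(vapply(labels, function(l)
            .js_divergence(rec_panel$p_at_40, mod_panels[[l]]$p_at_40), 0))],
        error = function(e) NA_character_)
    verdicts$avalanches <- if (is.null(lik)) NA_character_ else lik$model[1]
    verdicts$rsc <- tryCatch({
        ref <- rec_panel$rsc$mean_rsc
        labels[which.min(vapply(labels, function(l)
            mean(abs(mod_panels[[l]]$rsc$mean_rsc - ref), na.rm = TRUE), 0))]
    }, error = function(e) NA_character_)

    structure(list(recording = list(panels = rec_panel,
                                    n = models$n, rate = models$rate,
                                    n_bins = length(rec_act$counts)),
                   models = mod_panels, likelihood = lik,
                   verdicts = verdicts,
                   run_length = run_length, dt = dt,
                   seeds = seed + seq_along(labels)),
              class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
    cat("Validation report\n")
    cat(sprintf("  recording: n = %d units, R = %.3f Hz, %d bins of %g ms\n",
                x$recording$n, x$recording$rate, x$recording$n_bins, x$dt))
    cat("  closest model per panel:\n")
    for (nm in names(x$verdicts))
        cat(sprintf("    %-14s %s\n", nm, x$verdicts[[nm]]))
    invisible(x)
}

#' Full analysis pipeline for a spike recording
#'
#' One call from raster to report: bin the spikes, run MR estimation with
#' bootstrap confidence intervals and the consistency battery, build the
#' three matched surrogates, validate the recording against them, and
#' attach the closed-form predictions (state summary) plus a 500-trial
#' perturbation ensemble at the estimated state.  A failed consistency
#' battery downgrades `status` to `"estimates unreliable"` instead of
#' aborting.
#'
#' @param recording a [spike_raster()].
#' @param dt bin width in ms (default 4).
#' @param k_max lag range for MR estimation (default 150; choose
#'   `k_max * dt` spanning several expected timescales).
#' @param N surrogate network size.
#' @param B bootstrap replicates for the confidence interval (0 skips).
#' @param run_length surrogate run length in bins (see
#'   [validate_recording()]).
#' @param trials perturbation trials (default 500).
#' @param seed master seed.
#' @param consistency run the consistency battery (default TRUE).
#' @return A list of class `full_report`: `estimate`, `consistency`,
#'   `models`, `validation`, `state`, `perturbation`, `status`.
#' @export
full_report <- function(recording, dt = 4, k_max = 150, N = 10000L,
                        B = 0L, run_length = NULL, trials = 500L,
                        seed = 1L, consistency = TRUE) {
    stopifnot(inherits(recording, "spike_raster"))
    act <- bin_spikes(recording, dt = dt)
    est <- mr_estimate(act, k_max = k_max)
    models <- match_models(act, m_hat = est$m_hat, N = N, dt = dt,
                           seed = seed)
    if (B > 0) {
        pboot <- models$reverberating
        pboot$L <- as.integer(length(act$counts))
        est <- confidence_interval(est, pboot, B = B, seed = seed + 100L)
    }
    cons <- NULL
    status <- "ok"
    if (consistency) {
        cons <- tryCatch(consistency_tests(act, k_max = k_max, N = N,
                                           seed = seed + 200L),
                         error = function(e) NULL)
        if (is.null(cons) || !isTRUE(cons$passed))
            status <- "estimates unreliable"
    }
    validation <- validate_recording(recording, models,
                                     run_length = run_length,
                                     seed = seed + 300L)
    m_state <- min(max(est$m_hat, 0), 1 - 1e-6)
    state <- state_summary(m_state, dt = dt)
    pert <- perturbation_cascade(m_state, trials = trials, dt = dt,
                                 seed = seed + 400L)
    structure(list(estimate = est, consistency = cons, models = models,
                   validation = validation, state = state,
                   perturbation = pert, status = status, seed = seed),
              class = "full_report")
}

#' @export
print.full_report <- function(x, ...) {
    cat(sprintf("Full report (status: %s)\n", x$status))
    print(x$estimate)
    print(x$state)
    cat("  closest model per panel:",
        paste(unlist(x$validation$verdicts), collapse = ", "), "\n")
    invisible(x)
}
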