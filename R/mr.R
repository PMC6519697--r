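#' Multistep regression slopes of binned activity
#'
#' For each lag `k = 1..k_max` computes the ordinary-least-squares slope
#' `r_k` of `a_{t+k}` regressed on `a_t`, over all valid pairs from the
#' full trace.  Means are re-estimated per lag from the pairs actually
#' used.  For a stationary branching process these slopes follow
#' `r_k = b * m^k`, where the subsampling factor `b` scales the amplitude
#' but leaves the geometric decay in `m` untouched — the property that
#' makes the multistep-regression estimator subsampling invariant.
#'
#' @param activity a [binned_activity()] (or bare numeric vector with
#'   `dt` given).
#' @param k_max largest lag in bins (>= 2 for a subsequent exponential
#'   fit).  Choose `k_max * dt` to span several intrinsic timescales.
#' @param dt bin width in ms when `activity` is a bare vector.
#' @return An object of class `regression_slopes`: `lags`, `slopes`,
#'   `n_pairs`, `dt`.
#' @export
regression_slopes <- function(activity, k_max, dt = NULL) {
    if (inherits(activity, "binned_activity")) {
        x <- as.numeric(activity$counts); dt <- activity$dt
    } else {
        x <- as.numeric(activity)
        if (is.null(dt)) stop("supply dt for a bare numeric trace")
    }
    L <- length(x)
    stopifnot(k_max >= 1, L > k_max + 1)
    if (stats::var(x) == 0)
        stop("activity has zero variance; slopes undefined (degenerate input)")
    # per-lag OLS slope from exact running sums:
    # r_k = [S_xy - n*xbar*ybar] / [S_xx - n*xbar^2] over the n = L-k pairs
    cs <- c(0, cumsum(x))
    cs2 <- c(0, cumsum(x^2))
    k <- seq_len(k_max)
    n_pairs <- L - k
    sum_x <- cs[L - k + 1L]               # sum of x_1..x_{L-k}
    sum_y <- cs[L + 1L] - cs[k + 1L]      # sum of x_{k+1}..x_L
    sum_xx <- cs2[L - k + 1L]
    sum_xy <- .cross_sums_cpp(x, as.integer(k_max))
    ssx <- sum_xx - sum_x^2 / n_pairs
    slopes <- (sum_xy - sum_x * sum_y / n_pairs) / ssx
    if (any(!is.finite(slopes)))
        stop("non-finite slope encountered (constant segment at some lag)")
    structure(list(lags = seq_len(k_max), slopes = slopes,
                   n_pairs = n_pairs, dt = dt),
              class = "regression_slopes")
}

#' @export
print.regression_slopes <- function(x, ...) {
    cat(sprintf("Regression slopes r_k, k = 1..%d (dt = %g ms)\n",
                max(x$lags), x$dt))
    cat("  r_1 =", signif(x$slopes[1], 4), "\n")
    invisible(x)
}

# Gauss-Newton refinement of least squares r_k ~ b * m^k, analytic Jacobian.
# Converges to machine precision on noiseless geometric input.
.gn_polish <- function(k, r, b, m, m_upper, iters = 60) {
    b <- unname(b); m <- unname(m)
    for (i in seq_len(iters)) {
        g <- m^k
        e <- r - b * g
        J <- cbind(g, b * k * m^(k - 1))
        step <- tryCatch(solve(crossprod(J), crossprod(J, e)),
                         error = function(e2) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        b_new <- b + step[1]
        m_new <- min(max(m + step[2], 1e-10), m_upper)
        if (abs(b_new - b) < 1e-15 && abs(m_new - m) < 1e-15) {
            b <- b_new; m <- m_new; break
        }
        b <- b_new; m <- m_new
    }
    c(b = b, m = m)
}

# profile SSE over m (b solved in closed form); returns c(b, m, sse)
.profile_fit <- function(k, r, m_grid, m_upper) {
    sse_of <- function(m) {
        g <- m^k
        b <- sum(r * g) / sum(g * g)
        sum((r - b * g)^2)
    }
    sse <- vapply(m_grid, sse_of, 0)
    m0 <- m_grid[which.min(sse)]
    lo <- max(min(m_grid), m0 - 0.01); hi <- min(m_upper, m0 + 0.01)
    opt <- stats::optimize(sse_of, c(lo, hi), tol = 1e-12)
    m <- opt$minimum
    g <- m^k
    b <- sum(r * g) / sum(g * g)
    c(b = b, m = m, sse = opt$objective)
}

#' Fit the geometric decay of regression slopes (MR estimation)
#'
#' Least-squares fit of `r_k = b * m^k` jointly in `(b, m)`, with the
#' subsampling amplitude `b` partialled out so that `m` is estimated
#' without knowledge of the degree of subsampling.  The fit profiles the
#' error over `m` (with the optimal `b` in closed form), seeded from a
#' log-linear regression on the positive slopes plus fallback starts, and
#' is polished by Gauss-Newton iteration.  Negative slopes at large lags
#' are retained: truncating them would bias `m` upward.
#'
#' When the slopes carry no detectable decay at all (the geometric model
#' fails to beat the zero-slope null by BIC, as for uncorrelated Poisson
#' activity) the fitted `m` would be arbitrary noise alignment; the
#' estimate then falls back to the lag-1 slope, sets `b = 0`, and carries
#' the flag `"no_decay"`.
#'
#' The intrinsic network timescale follows as `tau = -dt/ln(m)`.
#'
#' @param slopes a [regression_slopes()] object.
#' @param m_upper upper bound for `m` (default 1.2; estimates above 1 are
#'   returned but flagged, they signal non-stationarity).
#' @return An object of class `mr_estimate` with `m_hat`, `tau_hat` (ms),
#'   `b_hat`, `residuals`, `slopes`, and diagnostic `flags`.
#' @examples
#' k <- 1:150
#' sl <- structure(list(lags = k, slopes = 0.5 * 0.98^k,
#'                      n_pairs = rep(1000L, 150), dt = 4),
#'                 class = "regression_slopes")
#' fit_exponential(sl)$m_hat # 0.98
#' @export
fit_exponential <- function(slopes, m_upper = 1.2) {
    stopifnot(inherits(slopes, "regression_slopes"))
    k <- slopes$lags; r <- slopes$slopes
    if (length(k) < 2) stop("need at least 2 lags for an exponential fit")
    sse_of <- function(b, m) sum((r - b * m^k)^2)

    starts <- list()
    pos <- r > 0
    if (sum(pos) >= 2) {
        co <- stats::coef(stats::lm(log(r[pos]) ~ k[pos]))
        m_init <- exp(co[2])
        if (is.finite(m_init) && m_init > 0)
            starts <- c(starts, list(min(m_init, m_upper - 1e-6)))
    }
    starts <- c(starts, list(0.5, 0.9, 0.99))

    m_grid <- seq(0.005, m_upper - 0.005, by = 0.005)
    best <- .profile_fit(k, r, m_grid, m_upper)
    for (s in starts) {
        cand <- .profile_fit(k, r, seq(max(0.001, s - 0.02),
                                       min(m_upper - 1e-6, s + 0.02),
                                       length.out = 9), m_upper)
        if (cand["sse"] < best["sse"]) best <- cand
    }
    pol <- .gn_polish(k, r, best["b"], best["m"], m_upper)
    if (sse_of(pol["b"], pol["m"]) <= best["sse"] + 1e-15) {
        b_hat <- unname(pol["b"]); m_hat <- unname(pol["m"])
    } else {
        b_hat <- unname(best["b"]); m_hat <- unname(best["m"])
    }
    if (!is.finite(m_hat) || !is.finite(b_hat))
        stop("exponential fit failed to converge (non-finite estimates); ",
             "inspect the slope sequence")
    flags <- character()
    # Guard against fitting pure noise: when the geometric model does not
    # beat the zero-slope null by BIC, the decay is undetectable and the
    # fitted m would be arbitrary.  Report the lag-1 slope instead (~0 for
    # uncorrelated activity) and flag it.
    n <- length(k)
    rss1 <- sse_of(b_hat, m_hat)
    rss0 <- sum(r^2)
    if (n * log(max(rss0, 1e-300) / n) <=
        n * log(max(rss1, 1e-300) / n) + 2 * log(n)) {
        m_hat <- r[1]
        b_hat <- 0
        flags <- c(flags, "no_decay")
        tau_hat <- if (m_hat > 0 && m_hat < 1) -slopes$dt / log(m_hat) else 0
        return(structure(list(m_hat = m_hat, tau_hat = tau_hat,
                              b_hat = b_hat, residuals = r, slopes = slopes,
                              dt = slopes$dt, k_max = max(k), flags = flags,
                              ci = NULL),
                         class = "mr_estimate"))
    }
    if (m_hat >= 1) flags <- c(flags, "m_ge_1")
    if (m_hat >= m_upper - 1e-6 || m_hat <= 1e-8)
        flags <- c(flags, "boundary")
    if (b_hat > 1) flags <- c(flags, "b_gt_1")
    tau_hat <- if (m_hat > 0 && m_hat < 1) -slopes$dt / log(m_hat) else Inf
    structure(list(m_hat = m_hat, tau_hat = tau_hat, b_hat = b_hat,
                   residuals = r - b_hat * m_hat^k, slopes = slopes,
                   dt = slopes$dt, k_max = max(k), flags = flags,
                   ci = NULL),
              class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
    cat("Multistep-regression estimate\n")
    cat(sprintf("  m_hat = %.4f, tau_hat = %.1f ms, b_hat = %.3f (k_max = %d, dt = %g ms)\n",
                x$m_hat, x$tau_hat, x$b_hat, x$k_max, x$dt))
    if (!is.null(x$ci))
        cat(sprintf("  m 5-95%% CI: [%.4f, %.4f]\n",
                    x$ci$m_5_95[1], x$ci$m_5_95[2]))
    if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
    invisible(x)
}

#' One-call MR estimation from binned activity
#'
#' Convenience wrapper: [regression_slopes()] followed by
#' [fit_exponential()].
#'
#' @inheritParams regression_slopes
#' @inheritParams fit_exponential
#' @return An `mr_estimate` (see [fit_exponential()]).
#' @export
mr_estimate <- function(activity, k_max, dt = NULL, m_upper = 1.2) {
    fit_exponential(regression_slopes(activity, k_max, dt), m_upper = m_upper)
}

#' Conventional (lag-one) branching-ratio estimator
#'
#' The classical full-sampling estimator: the lag-1 regression slope of
#' `a_{t+1}` on `a_t`.  Unbiased when the whole network is observed, but
#' severely biased towards 0 under subsampling, which is what motivates
#' the multistep-regression estimator.
#'
#' @inheritParams regression_slopes
#' @return The lag-1 slope (numeric scalar).
#' @export
conventional_estimate <- function(activity, dt = NULL) {
    regression_slopes(activity, k_max = 1, dt = dt)$slopes[1]
}

#' Parametric-bootstrap confidence intervals for an MR estimate
#'
#' Simulates `B` realizations of the matched branching network (same
#' `m = m_hat`, rate, sampled units and length as the data), re-estimates
#' `m` on each, and returns 16-84% and 5-95% quantile intervals for `m`
#' and `tau`.  Replicates whose fit fails are excluded and counted; more
#' than 20% failures is an error.
#'
#' @param estimate an `mr_estimate`.
#' @param params matched [branching_params()] (typically `m = m_hat`,
#'   `h` from [solve_input_rate()], same `n` and `L` as the data).
#' @param B number of bootstrap replicates (default 100).
#' @param seed seed for the bootstrap stream.
#' @param type `"basic"` (reflected, default — cancels first-order
#'   estimator bias such as the finite-network collision shift) or
#'   `"percentile"` (the raw replicate quantiles, matching shaded-spread
#'   displays).
#' @return The `estimate` with a `ci` element: `m_16_84`, `m_5_95`,
#'   `tau_16_84`, `tau_5_95`, `replicates`, `n_failed`, `type`.
#' @export
confidence_interval <- function(estimate, params, B = 100, seed = 1L,
                                type = c("basic", "percentile")) {
    stopifnot(inherits(estimate, "mr_estimate"),
              inherits(params, "branching_params"), B >= 2)
    type <- match.arg(type)
    k_max <- estimate$k_max
    reps <- numeric(0); failed <- 0L
    for (b in seq_len(B)) {
        pb <- params; pb$seed <- as.integer(seed + b)
        mh <- tryCatch({
            run <- simulate_network(pb, raster = FALSE)
            mr_estimate(run$sampled_counts, k_max = k_max)$m_hat
        }, error = function(e) NA_real_)
        if (is.na(mh)) failed <- failed + 1L else reps <- c(reps, mh)
    }
    if (failed > 0.2 * B)
        stop(failed, " of ", B, " bootstrap replicates failed to fit")
    tau <- -params$dt / log(pmin(pmax(reps, 1e-12), 1 - 1e-12))
    iv <- function(x, center, lo, hi) {
        q <- stats::quantile(x, c(lo, hi), names = FALSE)
        if (type == "percentile") q else sort(2 * center - rev(q))
    }
    estimate$ci <- list(
        m_16_84 = iv(reps, estimate$m_hat, 0.16, 0.84),
        m_5_95 = iv(reps, estimate$m_hat, 0.05, 0.95),
        tau_16_84 = iv(tau, estimate$tau_hat, 0.16, 0.84),
        tau_5_95 = iv(tau, estimate$tau_hat, 0.05, 0.95),
        replicates = reps, n_failed = failed, B = B, type = type)
    estimate
}

# Brown-Forsythe / Levene variance-equality test for two groups:
# one-way ANOVA on absolute deviations from the group center.
levene_test <- function(x, y, center = stats::median) {
    zx <- abs(x - center(x)); zy <- abs(y - center(y))
    z <- c(zx, zy); g <- factor(rep(1:2, c(length(zx), length(zy))))
    n <- length(z); kg <- 2L
    zbar <- mean(z); means <- tapply(z, g, mean)
    ssb <- sum(tabulate(g) * (means - zbar)^2)
    ssw <- sum((z - means[g])^2)
    Fstat <- (ssb / (kg - 1)) / (ssw / (n - kg))
    p <- stats::pf(Fstat, kg - 1, n - kg, lower.tail = FALSE)
    list(statistic = Fstat, p.value = p)
}

#' Windowed MR estimates and stationarity check
#'
#' Splits the trace into non-overlapping windows of `window` seconds,
#' estimates `m` in each, and (when matched parameters are supplied)
#' compares the window-to-window variability against the identical
#' procedure applied to realizations of the matched stationary model,
#' using a Levene (Brown-Forsythe) variance-equality test.  A small
#' p-value indicates more (or less) variability than a stationary model
#' of the same state produces — a signature of non-stationarity.
#'
#' @param activity a [binned_activity()].
#' @param window window length in seconds (must span >= 100 bins).
#' @param k_max lag range per window.
#' @param matched optional matched [branching_params()]; when given, the
#'   Levene comparison is run against `matched_reps` model realizations.
#' @param matched_reps number of matched-model realizations pooled into
#'   the comparison group (default 1, as in a single matched surrogate).
#' @param seed seed for the matched realizations.
#' @return A `consistency_report` list: `window_m` (per-window
#'   estimates), `model_window_m`, `variability_p`, `n_windows`,
#'   `passed` (p >= 0.05, `NA` when no matched model given).
#' @export
window_estimates <- function(activity, window = 5, k_max = 150,
                             matched = NULL, matched_reps = 1L, seed = 1L) {
    stopifnot(inherits(activity, "binned_activity"))
    bins_per <- floor(window * 1000 / activity$dt)
    if (bins_per < 100) stop("window must span at least 100 bins")
    n_win <- as.integer(length(activity$counts) %/% bins_per)
    if (n_win < 2) stop("need at least 2 windows")
    est_windows <- function(counts) {
        vapply(seq_len(length(counts) %/% bins_per), function(w) {
            seg <- counts[((w - 1) * bins_per + 1):(w * bins_per)]
            tryCatch(mr_estimate(seg, k_max = min(k_max, bins_per %/% 3),
                                 dt = activity$dt)$m_hat,
                     error = function(e) NA_real_)
        }, 0)
    }
    wm <- est_windows(activity$counts)
    model_wm <- NULL; p <- NA_real_
    if (!is.null(matched)) {
        stopifnot(inherits(matched, "branching_params"))
        model_wm <- unlist(lapply(seq_len(matched_reps), function(i) {
            pm <- matched
            pm$L <- as.integer(n_win * bins_per)
            pm$seed <- as.integer(seed + i)
            run <- simulate_network(pm, raster = FALSE)
            est_windows(run$sampled_counts$counts)
        }))
        p <- levene_test(wm[!is.na(wm)], model_wm[!is.na(model_wm)])$p.value
    }
    structure(list(window_m = wm, model_window_m = model_wm,
                   variability_p = p, n_windows = n_win,
                   window_s = window,
                   passed = if (is.na(p)) NA else p >= 0.05),
              class = "consistency_report")
}

#' Subsampling-invariance curve of the MR estimator
#'
#' For each subset size `n'`, repeatedly draws a fixed random subset of
#' the run's sampled units, re-estimates `m`, and summarizes the spread.
#' For a branching network the median curve is flat in `n'` — the
#' estimator's defining property — whereas the conventional lag-1
#' estimator decays towards 0.
#'
#' @param run a `network_run` carrying a raster.
#' @param subset_sizes integer vector of subset sizes `n'`.
#' @param repeats subset draws per size (default 20).
#' @param k_max lag range.
#' @param seed base seed for the subset draws.
#' @return A data.frame with one row per size: `n_prime`, `median_m`,
#'   `q16`, `q84`, plus attribute `"estimates"` (the full matrix).
#' @export
subsampling_invariance_curve <- function(run, subset_sizes, repeats = 20,
                                         k_max = 150, seed = 1L) {
    stopifnot(inherits(run, "network_run"))
    est <- matrix(NA_real_, nrow = repeats, ncol = length(subset_sizes))
    for (j in seq_along(subset_sizes)) {
        for (i in seq_len(repeats)) {
            a <- subsample(run, subset_sizes[j],
                           seed = seed + 1000L * j + i)
            est[i, j] <- tryCatch(mr_estimate(a, k_max = k_max)$m_hat,
                                  error = function(e) NA_real_)
        }
    }
    out <- data.frame(
        n_prime = subset_sizes,
        median_m = apply(est, 2, stats::median, na.rm = TRUE),
        q16 = apply(est, 2, stats::quantile, probs = 0.16, na.rm = TRUE),
        q84 = apply(est, 2, stats::quantile, probs = 0.84, na.rm = TRUE))
    attr(out, "estimates") <- est
    out
}

# exponential-plus-offset fit r_k = b*m^k + c, profiled over m
.fit_exp_offset <- function(k, r, m_upper = 1.2) {
    sse_of <- function(m) {
        X <- cbind(m^k, 1)
        f <- stats::lm.fit(X, r)
        sum(f$residuals^2)
    }
    grid <- seq(0.005, m_upper - 0.005, by = 0.005)
    sse <- vapply(grid, sse_of, 0)
    m0 <- grid[which.min(sse)]
    opt <- stats::optimize(sse_of, c(max(0.001, m0 - 0.01),
                                     min(m_upper, m0 + 0.01)), tol = 1e-10)
    list(m = opt$minimum, sse = opt$objective)
}

# least-squares power law a * k^e (log-log seeded, Gauss-Newton polished);
# inapplicable (infinite error) when any slope is non-positive
.fit_powerlaw <- function(k, r) {
    if (any(r <= 0)) return(list(sse = Inf))
    co <- stats::coef(stats::lm(log(r) ~ log(k)))
    a <- exp(co[1]); e <- co[2]
    for (i in 1:30) {
        g <- k^e
        res <- r - a * g
        J <- cbind(g, a * g * log(k))
        step <- tryCatch(solve(crossprod(J), crossprod(J, res)),
                         error = function(x) NULL)
        if (is.null(step) || any(!is.finite(step))) break
        a <- a + step[1]; e <- e + step[2]
        if (max(abs(step)) < 1e-12) break
    }
    list(sse = sum((r - a * k^e)^2), a = a, e = e)
}

#' Fit-adequacy check for a slope sequence
#'
#' Compares four descriptions of the regression slopes `r_k` by BIC:
#' geometric decay `b*m^k`, geometric decay plus offset `b*m^k + c`, a
#' power law `a*k^e`, and a constant.  MR estimation is adequate only
#' when the geometric family wins; power-law-like or flat sequences
#' fail.
#'
#' @param slopes a [regression_slopes()] object.
#' @return A list: `pass` (logical), `bic` (named vector), `best`.
#' @export
fit_adequacy <- function(slopes) {
    stopifnot(inherits(slopes, "regression_slopes"))
    k <- slopes$lags; r <- slopes$slopes; n <- length(k)
    fit <- fit_exponential(slopes)
    bic <- function(rss, p) n * log(max(rss, 1e-300) / n) + p * log(n)
    off <- .fit_exp_offset(k, r)
    pl <- .fit_powerlaw(k, r)
    bics <- c(exp = bic(sum(fit$residuals^2), 2),
              exp_offset = bic(off$sse, 3),
              powerlaw = if (is.finite(pl$sse)) bic(pl$sse, 2) else Inf,
              const = bic(sum((r - mean(r))^2), 1))
    best <- names(bics)[which.min(bics)]
    list(pass = best %in% c("exp", "exp_offset"), bic = bics, best = best)
}

#' Consistency battery for MR estimation
#'
#' Three conservative checks that reject traces showing common
#' non-stationarities, applied before trusting an MR estimate:
#' \describe{
#'   \item{fit_adequacy}{the slope sequence `r_k` must be better
#'     described (by BIC) by a geometric decay (with or without offset)
#'     than by a constant — power-law-like or flat slope sequences
#'     fail;}
#'   \item{stationarity}{window-to-window variability of `m_hat` must be
#'     statistically compatible (Levene test, alpha = 0.05) with a
#'     matched stationary model;}
#'   \item{trend}{no monotone trend in the windowed mean rate (Spearman
#'     rank test, alpha = 0.05).}
#' }
#' The battery is an explicit approximation of the conservative test set
#' used with the estimator; exact pass criteria are documented choices.
#'
#' @inheritParams window_estimates
#' @param N network size for the internally matched model (default 1e4).
#' @return A list of logical flags `fit_adequacy`, `stationarity`,
#'   `trend`, overall `passed`, and supporting numbers.
#' @export
consistency_tests <- function(activity, k_max = 150, window = 5,
                              N = 10000L, seed = 1L) {
    stopifnot(inherits(activity, "binned_activity"))
    sl <- regression_slopes(activity, k_max = k_max)
    fit <- fit_exponential(sl)
    adequacy <- fit_adequacy(sl)
    fit_ok <- adequacy$pass
    bics <- adequacy$bic

    n_units <- if (is.na(activity$n_units)) 1L else activity$n_units
    rate <- mean(activity$counts) / n_units / (activity$dt / 1000)
    m_for_matched <- min(max(fit$m_hat, 1e-4), 0.999)
    matched <- branching_params(m = m_for_matched, rate = rate, N = N,
                                n = n_units, dt = activity$dt,
                                L = length(activity$counts), seed = seed)
    win <- tryCatch(window_estimates(activity, window = window,
                                     k_max = k_max, matched = matched,
                                     seed = seed),
                    error = function(e) NULL)
    stat_ok <- if (is.null(win)) NA else isTRUE(win$passed)

    bins_per <- floor(window * 1000 / activity$dt)
    n_win <- length(activity$counts) %/% bins_per
    rates <- vapply(seq_len(n_win), function(w)
        mean(activity$counts[((w - 1) * bins_per + 1):(w * bins_per)]), 0)
    tr <- suppressWarnings(
        stats::cor.test(seq_len(n_win), rates, method = "spearman"))
    trend_ok <- tr$p.value >= 0.05

    list(fit_adequacy = fit_ok, stationarity = stat_ok, trend = trend_ok,
         passed = isTRUE(fit_ok) && isTRUE(stat_ok) && isTRUE(trend_ok),
         bic = bics, variability_p = if (is.null(win)) NA else win$variability_p,
         trend_p = tr$p.value, estimate = fit)
}
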