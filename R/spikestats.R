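#' Inter-spike-interval statistics per unit
#'
#' Sorted ISIs per unit, a pooled histogram, and the per-unit coefficient
#' of variation CV = sd(ISI)/mean(ISI).  A homogeneous Poisson unit has
#' exponential ISIs and CV = 1; a clock-like unit has CV = 0.  Units with
#' fewer than 2 spikes carry no interval and are excluded (and listed).
#'
#' @param raster a [spike_raster()].
#' @param breaks histogram breaks in seconds (default: 50 bins up to the
#'   99th percentile of pooled ISIs).
#' @return A list: `isi` (per-unit list of ISIs, seconds), `cv` (named
#'   per-unit CVs), `pooled_hist` (a [hist()]-style list), `excluded`
#'   (unit ids with < 2 spikes).
#' @export
isi_statistics <- function(raster, breaks = NULL) {
    stopifnot(inherits(raster, "spike_raster"))
    sp <- split(raster$time, raster$unit)
    n_spk <- lengths(sp)
    excluded <- names(sp)[n_spk < 2]
    sp <- sp[n_spk >= 2]
    if (length(sp) == 0) stop("no unit has >= 2 spikes")
    isi <- lapply(sp, function(t) diff(sort(t)))
    cv <- vapply(isi, function(d)
        if (length(d) >= 2) stats::sd(d) / mean(d) else NA_real_, 0)
    pooled <- unlist(isi, use.names = FALSE)
    if (is.null(breaks))
        breaks <- seq(0, stats::quantile(pooled, 0.99) * 1.02,
                      length.out = 51)
    h <- graphics::hist(pooled[pooled <= max(breaks)], breaks = breaks,
                        plot = FALSE)
    list(isi = isi, cv = cv, pooled_hist = h,
         excluded = as.integer(excluded))
}

#' Fano factor as a function of bin size
#'
#' F = Var(count)/mean(count) over non-overlapping windows of each
#' requested size (trailing partial windows dropped).  Scope
#' `"single_unit"` computes F per unit from a raster and reports the
#' median across units; `"population"` and `"full_network"` operate on a
#' summed count trace.  F is approximately 1 at all bin sizes for Poisson
#' activity; temporal correlations inflate it with growing bin size.
#'
#' @param x a [spike_raster()] (single-unit scope) or [binned_activity()].
#' @param bin_sizes bin sizes in ms (multiples of the native `dt` for
#'   binned input).
#' @param scope `"single_unit"`, `"population"`, or `"full_network"`.
#' @param dt native bin width used to bin a raster (default 4 ms).
#' @return A data.frame `bin_size`, `fano` (plus `n_units` for the
#'   single-unit scope), of class `fano_curve`.
#' @export
fano_factor <- function(x, bin_sizes, scope = c("single_unit", "population",
                                                "full_network"), dt = 4) {
    scope <- match.arg(scope)
    if (scope == "single_unit") {
        stopifnot(inherits(x, "spike_raster"))
        mat <- unit_count_matrix(x, dt = min(bin_sizes))
        out <- lapply(bin_sizes, function(bs) {
            f <- as.integer(round(bs / min(bin_sizes)))
            n <- (ncol(mat) %/% f) * f
            if (n %/% f < 10)
                stop("trace shorter than 10 bins at bin size ", bs, " ms")
            fano_u <- apply(mat[, seq_len(n), drop = FALSE], 1, function(row) {
                w <- colSums(matrix(row, nrow = f))
                mu <- mean(w)
                if (mu == 0) NA_real_ else stats::var(w) / mu
            })
            c(fano = stats::median(fano_u, na.rm = TRUE),
              n_units = sum(!is.na(fano_u)))
        })
        res <- data.frame(bin_size = bin_sizes,
                          fano = vapply(out, `[[`, 0, "fano"),
                          n_units = vapply(out, `[[`, 0, "n_units"))
    } else {
        stopifnot(inherits(x, "binned_activity"))
        res <- data.frame(bin_size = bin_sizes, fano = vapply(bin_sizes,
            function(bs) {
                a <- rebin(x, bs)
                if (length(a$counts) < 10)
                    stop("trace shorter than 10 bins at bin size ", bs, " ms")
                stats::var(a$counts) / mean(a$counts)
            }, 0))
    }
    attr(res, "scope") <- scope
    class(res) <- c("fano_curve", "data.frame")
    res
}

#' Empirical activity distribution p(a_t)
#'
#' Normalized histogram of spikes per bin after re-binning to the
#' requested bin size.
#'
#' @param activity a [binned_activity()].
#' @param bin_size bin size in ms (multiple of the native `dt`).
#' @return A data.frame `count`, `p` with `sum(p) == 1`.
#' @export
activity_distribution <- function(activity, bin_size = activity$dt) {
    stopifnot(inherits(activity, "binned_activity"))
    a <- rebin(activity, bin_size)
    tab <- tabulate(a$counts + 1L)
    data.frame(count = seq_along(tab) - 1L, p = tab / sum(tab))
}

#' Detect neuronal avalanches in a binned trace
#'
#' An avalanche is a maximal run of consecutive bins with nonzero
#' activity, separated by at least one empty bin (the standard
#' convention at the native bin width).  Size is the total number of
#' spikes in the run, duration its length in bins; hence every size >=
#' its duration, and the sizes sum exactly to the total spike count of
#' the occupied bins.
#'
#' @param activity a [binned_activity()].
#' @return An object of class `avalanche_set`: `sizes`, `durations`,
#'   `dt`, `n_avalanches`, and `single_run` flag (`TRUE` when the trace
#'   contains no empty bin, so one avalanche spans it).
#' @examples
#' a <- binned_activity(c(0, 2, 3, 0, 0, 1, 0), dt = 4)
#' detect_avalanches(a) # sizes 5, 1; durations 2, 1
#' @export
detect_avalanches <- function(activity) {
    stopifnot(inherits(activity, "binned_activity"))
    x <- activity$counts
    occ <- x > 0L
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    sizes <- mapply(function(s, e) sum(x[s:e]), starts[keep], ends[keep])
    structure(list(sizes = as.numeric(sizes),
                   durations = as.numeric(r$lengths[keep]),
                   dt = activity$dt, n_avalanches = sum(keep),
                   single_run = all(occ) && length(x) > 0),
              class = "avalanche_set")
}

#' @export
print.avalanche_set <- function(x, ...) {
    cat(sprintf("Avalanche set: %d avalanches (dt = %g ms)", x$n_avalanches,
                x$dt))
    if (x$n_avalanches > 0)
        cat(sprintf(", mean size %.2f, max size %g", mean(x$sizes),
                    max(x$sizes)))
    if (x$single_run) cat(" [single run spans trace]")
    cat("\n")
    invisible(x)
}

# empirical avalanche-size pmf with add-one smoothing on observed support
# and a geometric tail fitted to the top decade; returns a log-pmf function
.avalanche_size_logpmf <- function(sizes) {
    M <- max(sizes)
    cnt <- tabulate(sizes, nbins = M)
    sm <- cnt + 1
    # geometric tail rate from the top decade of the observed range
    lo <- max(1, floor(M / 10))
    kk <- lo:M
    g <- 0.5
    if (length(kk) >= 2) {
        fit <- stats::lm(log(sm[kk]) ~ kk)
        slope <- unname(stats::coef(fit)[2])
        if (is.finite(slope) && slope < 0)
            g <- min(exp(slope), 0.999999)
    }
    tail_at_M1 <- sm[M] * g            # unnormalized mass at M+1
    tail_total <- tail_at_M1 / (1 - g) # geometric series beyond M
    Z <- sum(sm) + tail_total
    log_body <- log(sm) - log(Z)
    function(s) {
        out <- numeric(length(s))
        inb <- s <= M
        out[inb] <- log_body[s[inb]]
        if (any(!inb))
            out[!inb] <- log(tail_at_M1) + (s[!inb] - M - 1) * log(g) - log(Z)
        out
    }
}

#' Avalanche-size likelihood comparison across candidate models
#'
#' Builds an empirical avalanche-size distribution from each candidate
#' model trace (add-one smoothing on the observed support plus a
#' geometric tail fitted to the top decade, so unseen large sizes keep
#' nonzero mass) and evaluates the log-likelihood of the data's avalanche
#' sizes under each.  Used to ask which matched model — asynchronous-
#' irregular, reverberating, or near-critical — best explains a
#' recording's avalanches.
#'
#' @param data an `avalanche_set` (the recording's avalanches).
#' @param candidates named list of [binned_activity()] traces (or
#'   `avalanche_set`s), one per candidate model.
#' @return A data.frame `model`, `loglik`, `loglik_per_avalanche`, ranked
#'   best first.
#' @export
avalanche_model_likelihood <- function(data, candidates) {
    stopifnot(inherits(data, "avalanche_set"), length(candidates) >= 1)
    if (is.null(names(candidates)))
        names(candidates) <- paste0("model", seq_along(candidates))
    ll <- vapply(candidates, function(cand) {
        av <- if (inherits(cand, "avalanche_set")) cand
              else detect_avalanches(cand)
        if (av$n_avalanches < 10)
            stop("candidate trace yields fewer than 10 avalanches")
        lpmf <- .avalanche_size_logpmf(av$sizes)
        sum(lpmf(data$sizes))
    }, 0)
    out <- data.frame(model = names(candidates), loglik = ll,
                      loglik_per_avalanche = ll / data$n_avalanches,
                      row.names = NULL)
    out[order(-out$loglik), ]
}

#' Pairwise spike-count cross-correlations vs bin size
#'
#' Mean over all unit pairs of the Pearson correlation of binned counts,
#' for each requested bin size.  Zero-variance units are excluded
#' pair-wise.  In branching networks r_sc grows with bin size because
#' slow shared rate fluctuations accumulate in larger windows.
#'
#' @param raster a [spike_raster()] with >= 2 units.
#' @param bin_sizes bin sizes in ms.
#' @param dt native bin width (ms) used internally.
#' @return A data.frame `bin_size`, `mean_rsc`, `n_pairs` of class
#'   `correlation_curve`.
#' @export
spike_count_correlation <- function(raster, bin_sizes, dt = 4) {
    stopifnot(inherits(raster, "spike_raster"))
    mat <- unit_count_matrix(raster, dt = min(c(bin_sizes, dt)))
    if (nrow(mat) < 2) stop("need at least 2 units")
    base_dt <- min(c(bin_sizes, dt))
    res <- lapply(bin_sizes, function(bs) {
        f <- as.integer(round(bs / base_dt))
        n <- (ncol(mat) %/% f) * f
        if (n %/% f < 10)
            stop("trace shorter than 10 bins at bin size ", bs, " ms")
        wm <- t(apply(mat[, seq_len(n), drop = FALSE], 1, function(row)
            colSums(matrix(row, nrow = f))))
        v <- apply(wm, 1, stats::var)
        wm <- wm[v > 0, , drop = FALSE]
        if (nrow(wm) < 2) return(c(r = NA_real_, np = 0))
        cc <- stats::cor(t(wm))
        c(r = mean(cc[upper.tri(cc)]), np = sum(upper.tri(cc)))
    })
    out <- data.frame(bin_size = bin_sizes,
                      mean_rsc = vapply(res, `[[`, 0, "r"),
                      n_pairs = vapply(res, `[[`, 0, "np"))
    class(out) <- c("correlation_curve", "data.frame")
    out
}

#' Normalized autocorrelation function with exponential-fit timescale
#'
#' Standard normalized autocorrelation of a count trace up to `max_lag`
#' bins.  For population activity of a branching network the function
#' decays as `exp(-lag*dt/tau)`; for single units, subsampling adds a
#' sharp drop from `r_0 = 1` to a low floor that still decays with the
#' same `tau` — so the exponential fit uses lags >= 1 by default.  A
#' naive fit that includes lag 0 (for comparison) returns a drastically
#' underestimated timescale on subsampled data.
#'
#' @param activity a [binned_activity()].
#' @param max_lag largest lag in bins (< half the trace length).
#' @param exclude_zero_lag if `TRUE` (default) the exponential fit uses
#'   lags 1..`max_lag` only.
#' @param fit if `TRUE`, fit the decay `b * exp(-lag*dt/tau)` and report
#'   `tau`.
#' @return A list of class `autocorrelation_curve`: `lags_ms`, `values`
#'   (including lag 0), `tau_ms`, `b`, and when `fit = TRUE` and
#'   `exclude_zero_lag = TRUE` also `tau_naive_ms` from the fit that
#'   includes lag 0.
#' @export
autocorrelation <- function(activity, max_lag, exclude_zero_lag = TRUE,
                            fit = TRUE) {
    stopifnot(inherits(activity, "binned_activity"))
    x <- as.numeric(activity$counts)
    if (max_lag >= length(x) / 2) stop("max_lag must be < trace length / 2")
    if (stats::var(x) == 0) stop("zero-variance trace")
    ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    out <- list(lags_ms = (0:max_lag) * activity$dt, values = ac,
                dt = activity$dt)
    if (fit) {
        fit_tau <- function(lags, vals) {
            sl <- structure(list(lags = lags, slopes = vals,
                                 n_pairs = rep.int(1L, length(lags)),
                                 dt = activity$dt),
                            class = "regression_slopes")
            f <- fit_exponential(sl)
            list(tau = f$tau_hat, b = f$b_hat, m = f$m_hat)
        }
        f1 <- fit_tau(1:max_lag, ac[-1])
        out$tau_ms <- f1$tau; out$b <- f1$b; out$m <- f1$m
        if (exclude_zero_lag) {
            # naive comparison: include the r_0 = 1 point in the fit
            f0 <- fit_tau(0:max_lag, ac)
            out$tau_naive_ms <- f0$tau
        }
    }
    class(out) <- "autocorrelation_curve"
    out
}

#' @export
print.autocorrelation_curve <- function(x, ...) {
    cat(sprintf("Autocorrelation over %d lags (dt = %g ms)",
                length(x$values) - 1L, x$dt))
    if (!is.null(x$tau_ms))
        cat(sprintf("; fitted tau = %.1f ms (b = %.3f)", x$tau_ms, x$b))
    cat("\n")
    invisible(x)
}
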