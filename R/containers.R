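#' Spike raster: per-unit spike times
#'
#' A minimal container for point-process spike data: integer unit ids and
#' spike times in seconds.  Rows need not be sorted; constructors sort by
#' time.  `t_end` records the recording length so that trailing empty
#' bins are representable.
#'
#' @param unit integer unit identifiers (non-negative).
#' @param time spike times in seconds (finite, >= 0).
#' @param t_end recording length in seconds; defaults to the last spike.
#' @param n_units number of units in the recording; defaults to the
#'   number of distinct ids seen (silent units are allowed by passing a
#'   larger value).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(unit, time, t_end = NULL, n_units = NULL) {
    stopifnot(length(unit) == length(time))
    if (length(time) == 0L) stop("empty raster")
    if (any(!is.finite(time)) || any(time < 0)) stop("spike times must be finite and >= 0")
    unit <- as.integer(unit)
    if (any(is.na(unit)) || any(unit < 0)) stop("unit ids must be non-negative integers")
    o <- order(time, unit)
    if (is.null(t_end)) t_end <- max(time)
    if (is.null(n_units)) n_units <- length(unique(unit))
    stopifnot(t_end >= max(time))
    structure(list(unit = unit[o], time = time[o],
                   n_units = as.integer(n_units), t_end = t_end),
              class = "spike_raster")
}

#' @export
print.spike_raster <- function(x, ...) {
    cat(sprintf("Spike raster: %d spikes, %d units, %.3f s", length(x$time),
                x$n_units, x$t_end))
    cat(sprintf(" (mean rate %.2f Hz/unit)\n",
                length(x$time) / x$n_units / x$t_end))
    invisible(x)
}

#' Binned population activity
#'
#' Integer spike counts per time bin of width `dt` ms, either for the
#' full network (`label = "full"`, the activity `A_t`) or for a sampled
#' subset of units (`label = "subsampled"`, the observed `a_t`).
#'
#' @param counts non-negative integer counts per bin.
#' @param dt bin width in milliseconds.
#' @param label `"full"` or `"subsampled"`.
#' @param n_units number of units contributing to the counts.
#' @return An object of class `binned_activity`.
#' @export
binned_activity <- function(counts, dt, label = c("subsampled", "full"),
                            n_units = NA_integer_) {
    label <- match.arg(label)
    counts <- as.integer(counts)
    if (any(is.na(counts)) || any(counts < 0))
        stop("counts must be non-negative integers")
    stopifnot(dt > 0)
    structure(list(counts = counts, dt = dt, label = label,
                   n_units = as.integer(n_units)),
              class = "binned_activity")
}

#' @export
print.binned_activity <- function(x, ...) {
    cat(sprintf("Binned activity (%s): %d bins of %g ms, mean %.3f spikes/bin",
                x$label, length(x$counts), x$dt, mean(x$counts)))
    if (!is.na(x$n_units)) cat(sprintf(", %d units", x$n_units))
    cat("\n")
    invisible(x)
}

#' Bin a spike raster into population counts
#'
#' Pools all units into one train and counts spikes per half-open bin
#' `[t*dt, (t+1)*dt)`.  A trailing partial bin (beyond the last complete
#' bin inside `t_end`) is dropped.
#'
#' @param raster a [spike_raster()].
#' @param dt bin width in milliseconds.
#' @return A [binned_activity()] with one count per complete bin.
#' @export
bin_spikes <- function(raster, dt = 4) {
    stopifnot(inherits(raster, "spike_raster"), dt > 0)
    dt_s <- dt / 1000
    n_bins <- floor(raster$t_end / dt_s + 1e-9)
    if (n_bins < 1L) stop("recording shorter than one bin")
    idx <- floor(raster$time / dt_s) + 1L
    keep <- idx <= n_bins
    counts <- tabulate(idx[keep], nbins = n_bins)
    binned_activity(counts, dt = dt, label = "subsampled",
                    n_units = raster$n_units)
}

#' Re-bin activity to a coarser bin width
#'
#' Sums consecutive native bins; the requested bin size must be an
#' integer multiple of the native `dt`.  A trailing partial group is
#' dropped.
#'
#' @param activity a [binned_activity()].
#' @param bin_size requested bin width in milliseconds.
#' @return A [binned_activity()] at the coarser resolution.
#' @export
rebin <- function(activity, bin_size) {
    stopifnot(inherits(activity, "binned_activity"))
    f <- bin_size / activity$dt
    if (abs(f - round(f)) > 1e-8)
        stop("bin_size must be a multiple of the native dt (", activity$dt, " ms)")
    f <- as.integer(round(f))
    if (f == 1L) return(activity)
    n <- (length(activity$counts) %/% f) * f
    if (n < f) stop("trace shorter than one requested bin")
    x <- activity$counts[seq_len(n)]
    counts <- colSums(matrix(x, nrow = f))
    binned_activity(counts, dt = bin_size, label = activity$label,
                    n_units = activity$n_units)
}

# per-unit binned count matrix (units x bins); used by single-unit statistics
unit_count_matrix <- function(raster, dt) {
    dt_s <- dt / 1000
    n_bins <- floor(raster$t_end / dt_s + 1e-9)
    idx <- floor(raster$time / dt_s) + 1L
    keep <- idx <= n_bins
    units <- sort(unique(raster$unit))
    ui <- match(raster$unit[keep], units)
    comb <- (idx[keep] - 1L) * length(units) + ui
    mat <- matrix(tabulate(comb, nbins = length(units) * n_bins),
                  nrow = length(units))
    rownames(mat) <- units
    mat
}
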