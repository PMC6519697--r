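#' Read a spike raster from delimited text
#'
#' Expects two tab- or whitespace-delimited columns, `unit_id` (integer)
#' and `spike_time` (seconds); lines starting with `#` are ignored.
#' Malformed lines are reported with their line numbers.
#'
#' @param path file path.
#' @param t_end recording length in seconds (default: last spike time).
#' @return A [spike_raster()].
#' @export
read_raster <- function(path, t_end = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    body <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
    if (!any(body)) stop("empty raster file: ", path)
    ln <- which(body)
    parts <- strsplit(trimws(lines[body]), "[\t ]+")
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
        stop("malformed line(s) at ", paste(ln[bad][seq_len(min(5,
             length(bad)))], collapse = ", "), " in ", path,
             " (expected 2 columns)")
    unit <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
    time <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    bad <- which(is.na(unit) | is.na(time))
    if (length(bad))
        stop("unparseable value(s) at line(s) ",
             paste(ln[bad][seq_len(min(5, length(bad)))], collapse = ", "),
             " in ", path)
    spike_raster(unit, time, t_end = t_end)
}

#' Write a spike raster as delimited text
#'
#' Two tab-separated columns (`unit_id`, `spike_time` with 6 decimals,
#' i.e. microsecond resolution) under a `#` header carrying provenance.
#'
#' @param raster a [spike_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
    stopifnot(inherits(raster, "spike_raster"))
    writeLines(c(sprintf("# spike raster: %d units, t_end = %.6f s",
                         raster$n_units, raster$t_end),
                 "# unit_id\tspike_time_s"), path)
    data.table::fwrite(data.table::data.table(raster$unit,
                           sprintf("%.6f", raster$time)),
                       path, sep = "\t", col.names = FALSE, append = TRUE)
    invisible(path)
}

#' Read / write binned count traces
#'
#' Counts are stored as plain integer text, either one column (`count`)
#' or two (`bin_index`, `count`); `#` lines are ignored.
#'
#' @param path file path.
#' @param dt bin width in ms of the stored counts.
#' @return `read_counts`: a [binned_activity()].
#' @export
read_counts <- function(path, dt = 4) {
    if (!file.exists(path)) stop("file not found: ", path)
    dt_tab <- data.table::fread(path, header = FALSE)
    counts <- if (ncol(dt_tab) >= 2L) dt_tab[[2L]] else dt_tab[[1L]]
    binned_activity(counts, dt = dt)
}

#' @rdname read_counts
#' @param activity a [binned_activity()].
#' @param index include a bin-index column (default FALSE).
#' @export
write_counts <- function(activity, path, index = FALSE) {
    stopifnot(inherits(activity, "binned_activity"))
    d <- if (index)
        data.table::data.table(seq_along(activity$counts) - 1L,
                               activity$counts)
    else data.table::data.table(activity$counts)
    data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Generate a deterministic synthetic recording with known ground truth
#'
#' Produces small synthetic spike rasters emulating the in-vivo-like
#' recording configuration (defaults: 295 s, n = 50 sampled units at
#' about 7.25 Hz each, network of N = 1e4 neurons), plus the ground-truth
#' metadata needed for assertions.  Kinds:
#' \describe{
#'   \item{AI}{asynchronous-irregular, `m = 0`;}
#'   \item{reverberating}{`m = 0.98`;}
#'   \item{near_critical}{`m = 0.9999`;}
#'   \item{step_change}{reverberating with the input rate doubling
#'     halfway through (a known non-stationarity);}
#'   \item{ramp}{reverberating with the rate ramping linearly to twice
#'     its initial value (ten piecewise segments).}
#' }
#'
#' @param kind fixture kind (see Details).
#' @param seed RNG seed; the same seed always yields the same fixture.
#' @param duration_s recording length in seconds.
#' @param n sampled units.
#' @param rate target per-unit rate in Hz.
#' @param N network size.
#' @param dt bin width in ms.
#' @return A list: `raster` (a [spike_raster()]) and `truth` (list with
#'   `kind`, `m`, `h`, `N`, `n`, `rate`, `dt`, `seed`).
#' @export
make_fixture <- function(kind = c("AI", "reverberating", "near_critical",
                                  "step_change", "ramp"),
                         seed = 1L, duration_s = 295, n = 50L,
                         rate = 7.25, N = 10000L, dt = 4) {
    kind <- match.arg(kind)
    m <- switch(kind, AI = 0, reverberating = 0.98, near_critical = 0.9999,
                step_change = 0.98, ramp = 0.98)
    L <- as.integer(round(duration_s * 1000 / dt))
    simulate_piece <- function(r, Lp, sd) {
        p <- branching_params(m = m, rate = r, N = N, n = n, dt = dt,
                              L = Lp, seed = sd)
        simulate_network(p, raster = TRUE)
    }
    if (kind %in% c("AI", "reverberating", "near_critical")) {
        run <- simulate_piece(rate, L, seed)
        ras <- run$sampled_raster
    } else {
        rates <- if (kind == "step_change") c(rate, 2 * rate)
                 else rate * seq(1, 2, length.out = 10)
        Lp <- L %/% length(rates)
        offset <- 0
        un <- integer(0); tm <- numeric(0)
        for (i in seq_along(rates)) {
            run <- simulate_piece(rates[i], Lp, seed + i)
            un <- c(un, run$sampled_raster$unit)
            tm <- c(tm, run$sampled_raster$time + offset)
            offset <- offset + Lp * dt / 1000
        }
        ras <- spike_raster(un, tm, t_end = offset, n_units = n)
    }
    list(raster = ras,
         truth = list(kind = kind, m = m,
                      h = if (m < 1) solve_input_rate(rate, dt, N, m)
                          else NA_real_,
                      N = N, n = n, rate = rate, dt = dt, seed = seed))
}
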