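#' Frequency grid for averaged vibration spectra
#'
#' A regular grid of spectral bins: bin \code{k} (0-based) sits at
#' \code{f0 + k * df} Hz.  The hive monitoring hardware this package models
#' exports power spectra at 3 Hz resolution, so the default grid starts at
#' 0 Hz with 3 Hz spacing.
#'
#' @param f0 start frequency in Hz of the first bin centre.
#' @param df bin spacing in Hz; must be positive.
#' @param n_bins number of bins; must be at least 1.
#' @return An object of class \code{freq_grid}.
#' @examples
#' g <- freq_grid(0, 3, 300)
#' head(grid_freqs(g))
#' @export
freq_grid <- function(f0 = 0, df = 3, n_bins = 1834) {
  stopifnot(is.numeric(f0), length(f0) == 1L, is.finite(f0))
  if (!is.numeric(df) || length(df) != 1L || !is.finite(df) || df <= 0)
    stop("'df' must be a positive number")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stop("'n_bins' must be >= 1")
  structure(list(f0 = as.numeric(f0), df = as.numeric(df), n_bins = n_bins),
            class = "freq_grid")
}

#' @rdname freq_grid
#' @param grid a \code{freq_grid}.
#' @export
grid_freqs <- function(grid) {
  stopifnot(inherits(grid, "freq_grid"))
  grid$f0 + grid$df * (seq_len(grid$n_bins) - 1)
}

#' @export
print.freq_grid <- function(x, ...) {
  cat(sprintf("<freq_grid> %d bins, %g to %g Hz (df = %g Hz)\n",
              x$n_bins, x$f0, x$f0 + (x$n_bins - 1) * x$df, x$df))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  abs(a$f0 - b$f0) < tol && abs(a$df - b$df) < tol && a$n_bins == b$n_bins
}

#' Single averaged vibration spectrum
#'
#' One timestamped power spectrum on a fixed frequency grid.  Spectra lost to
#' power cuts are represented explicitly with \code{quality = "missing"} and
#' are never stored as zero amplitudes.
#'
#' @param timestamp a POSIXct instant (minute precision is sufficient).
#' @param grid a \code{freq_grid}.
#' @param amplitudes non-negative numeric vector of length \code{grid$n_bins},
#'   in arbitrary power units; ignored (may be \code{NA}) when
#'   \code{quality = "missing"}.
#' @param quality \code{"ok"} or \code{"missing"}.
#' @return An object of class \code{spectrum_frame}.
#' @export
spectrum_frame <- function(timestamp, grid, amplitudes,
                           quality = c("ok", "missing")) {
  quality <- match.arg(quality)
  stopifnot(inherits(grid, "freq_grid"), inherits(timestamp, "POSIXct"))
  amplitudes <- as.numeric(amplitudes)
  if (length(amplitudes) != grid$n_bins)
    stop("length(amplitudes) must equal grid$n_bins")
  if (quality == "ok" && any(!is.finite(amplitudes) | amplitudes < 0))
    stop("'ok' frames require finite non-negative amplitudes")
  structure(list(timestamp = timestamp, grid = grid,
                 amplitudes = amplitudes, quality = quality),
            class = "spectrum_frame")
}

#' @export
print.spectrum_frame <- function(x, ...) {
  cat(sprintf("<spectrum_frame> %s [%s], %d bins\n",
              format(x$timestamp, "%Y-%m-%d %H:%M"), x$quality,
              x$grid$n_bins))
  invisible(x)
}

#' Time series of averaged vibration spectra for one colony
#'
#' Stores the full monitoring record of a colony: a strictly increasing
#' time vector, one shared frequency grid, an amplitude matrix with one row
#' per frame, and a per-frame quality flag.  The nominal cadence between
#' frames is 180 s (3-minute averaged spectra).
#'
#' @param colony_id character scalar naming the colony.
#' @param times POSIXct vector, strictly increasing.
#' @param grid a \code{freq_grid} shared by all frames.
#' @param amplitudes numeric matrix, \code{length(times)} rows by
#'   \code{grid$n_bins} columns.
#' @param quality character vector of \code{"ok"}/\code{"missing"}, recycled
#'   if length 1.
#' @param cadence nominal seconds between frames (default 180).
#' @return An object of class \code{spectra_series}.
#' @export
spectra_series <- function(colony_id, times, grid, amplitudes,
                           quality = "ok", cadence = 180) {
  stopifnot(is.character(colony_id), length(colony_id) == 1L,
            inherits(times, "POSIXct"), inherits(grid, "freq_grid"))
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != length(times))
    stop("amplitudes must have one row per time")
  if (ncol(amplitudes) != grid$n_bins)
    stop("amplitudes must have grid$n_bins columns")
  if (length(times) == 0L) stop("series must contain at least one frame")
  if (any(diff(as.numeric(times)) <= 0))
    stop("timestamps must be strictly increasing")
  quality <- rep_len(as.character(quality), length(times))
  if (!all(quality %in% c("ok", "missing")))
    stop("quality values must be 'ok' or 'missing'")
  ok <- quality == "ok"
  if (any(!is.finite(amplitudes[ok, , drop = FALSE])) ||
      any(amplitudes[ok, , drop = FALSE] < 0))
    stop("'ok' frames require finite non-negative amplitudes")
  structure(list(colony_id = colony_id, times = times, grid = grid,
                 amplitudes = amplitudes, quality = quality,
                 cadence = as.numeric(cadence)),
            class = "spectra_series")
}

#' @export
print.spectra_series <- function(x, ...) {
  cat(sprintf(
    "<spectra_series> colony '%s': %d frames (%d ok), %s to %s\n",
    x$colony_id, length(x$times), sum(x$quality == "ok"),
    format(min(x$times), "%Y-%m-%d %H:%M"),
    format(max(x$times), "%Y-%m-%d %H:%M")))
  print(x$grid)
  invisible(x)
}

#' @export
length.spectra_series <- function(x) length(x$times)

#' Extract one frame of a series
#'
#' @param series a \code{spectra_series}.
#' @param i frame index.
#' @return A \code{spectrum_frame}.
#' @export
series_frame <- function(series, i) {
  stopifnot(inherits(series, "spectra_series"))
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= length(series$times))
  spectrum_frame(series$times[i], series$grid, series$amplitudes[i, ],
                 quality = series$quality[i])
}

event_kinds <- c("primary_swarm", "afterswarm", "failed_swarm",
                 "hive_opening", "power_cut_start", "power_cut_end",
                 "toot_onset", "toot_cessation",
                 "quack_onset", "quack_cessation")

#' Colony event log
#'
#' Ground-truth record of colony events (swarms, hive openings, power cuts,
#' queen-pipe onsets and cessations) used for labelling and for checking pipe
#' chronology.
#'
#' @param time POSIXct vector of event times.
#' @param kind character vector drawn from the closed vocabulary
#'   \code{primary_swarm}, \code{afterswarm}, \code{failed_swarm},
#'   \code{hive_opening}, \code{power_cut_start}, \code{power_cut_end},
#'   \code{toot_onset}, \code{toot_cessation}, \code{quack_onset},
#'   \code{quack_cessation}.
#' @param note optional character annotations.
#' @return A data frame of class \code{event_log} with columns
#'   \code{time}, \code{kind}, \code{note}, sorted by time.
#' @export
event_log <- function(time = as.POSIXct(character(), tz = "UTC"),
                      kind = character(), note = "") {
  stopifnot(inherits(time, "POSIXct"))
  kind <- as.character(kind)
  if (!all(kind %in% event_kinds))
    stop("unknown event kind(s): ",
         paste(setdiff(kind, event_kinds), collapse = ", "))
  note <- rep_len(as.character(note), length(time))
  out <- data.frame(time = time, kind = kind, note = note,
                    stringsAsFactors = FALSE)
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_log", "data.frame")
  out
}

#' Hourly mean spectrum over a window of a day
#'
#' Element-wise arithmetic mean over the \code{ok} frames whose timestamps
#' fall in the half-open window \code{[day + start_hour, day + end_hour)}.
#' If the window contains no \code{ok} frame the returned frame has
#' \code{quality = "missing"}: gaps are never averaged in as zeros.
#'
#' @param series a \code{spectra_series}.
#' @param day a \code{Date}.
#' @param start_hour,end_hour integer hours of the local day;
#'   \code{end_hour} must exceed \code{start_hour}.
#' @return A \code{spectrum_frame} timestamped at the window start.
#' @export
hourly_average <- function(series, day, start_hour, end_hour) {
  stopifnot(inherits(series, "spectra_series"), inherits(day, "Date"))
  if (length(series$times) == 0L) stop("empty series")
  if (end_hour <= start_hour) stop("end_hour must exceed start_hour")
  t0 <- as.POSIXct(paste0(format(day), " 00:00:00"), tz = "UTC") +
    3600 * start_hour
  t1 <- as.POSIXct(paste0(format(day), " 00:00:00"), tz = "UTC") +
    3600 * end_hour
  sel <- series$times >= t0 & series$times < t1 & series$quality == "ok"
  if (!any(sel))
    return(spectrum_frame(t0, series$grid,
                          rep(NA_real_, series$grid$n_bins),
                          quality = "missing"))
  amp <- colMeans(series$amplitudes[sel, , drop = FALSE])
  spectrum_frame(t0, series$grid, amp, quality = "ok")
}

#' Crop a spectrum (or series) to a frequency band
#'
#' Keeps exactly the bins whose centre frequency lies in the closed interval
#' \code{[f_lo, f_hi]}; the grid is updated accordingly.  The swarm
#' classifiers crop to 18-800 Hz (instantaneous strategy, excluding sub-18 Hz
#' wind noise) or 25-800 Hz (spectral-evolution strategy).
#'
#' @param x a \code{spectrum_frame} or \code{spectra_series}.
#' @param f_lo,f_hi band edges in Hz, \code{f_lo < f_hi}.
#' @return An object of the same class as \code{x} on the cropped grid.
#' @export
crop_bandwidth <- function(x, f_lo, f_hi) UseMethod("crop_bandwidth")

crop_indices <- function(grid, f_lo, f_hi) {
  if (f_lo >= f_hi) stop("f_lo must be below f_hi")
  f <- grid_freqs(grid)
  keep <- which(f >= f_lo - 1e-9 & f <= f_hi + 1e-9)
  if (length(keep) == 0L)
    stop("crop interval [", f_lo, ", ", f_hi, "] contains no grid bins")
  keep
}

#' @export
crop_bandwidth.spectrum_frame <- function(x, f_lo, f_hi) {
  keep <- crop_indices(x$grid, f_lo, f_hi)
  f <- grid_freqs(x$grid)[keep]
  g <- freq_grid(f[1], x$grid$df, length(keep))
  spectrum_frame(x$timestamp, g, x$amplitudes[keep], quality = x$quality)
}

#' @export
crop_bandwidth.spectra_series <- function(x, f_lo, f_hi) {
  keep <- crop_indices(x$grid, f_lo, f_hi)
  f <- grid_freqs(x$grid)[keep]
  g <- freq_grid(f[1], x$grid$df, length(keep))
  out <- x
  out$grid <- g
  out$amplitudes <- x$amplitudes[, keep, drop = FALSE]
  out
}

#' Locate gaps in a series
#'
#' Returns the maximal intervals where data are absent, either because
#' consecutive timestamps differ by more than 1.5 times the nominal cadence
#' or because frames are flagged \code{missing}.  A frame missing at time
#' \code{t} contributes the interval \code{[t, t + cadence)}; a timestamp
#' jump from \code{t_i} to \code{t_j} contributes
#' \code{[t_i + cadence, t_j)}.  Touching intervals are merged.
#'
#' @param series a \code{spectra_series}.
#' @return A data frame with POSIXct columns \code{gap_start},
#'   \code{gap_end} (zero rows when the series is gap-free).
#' @export
scan_gaps <- function(series) {
  stopifnot(inherits(series, "spectra_series"))
  tt <- as.numeric(series$times)
  cad <- series$cadence
  starts <- numeric(0); ends <- numeric(0)
  miss <- which(series$quality == "missing")
  if (length(miss)) {
    starts <- c(starts, tt[miss])
    ends <- c(ends, tt[miss] + cad)
  }
  if (length(tt) > 1L) {
    dt <- diff(tt)
    jump <- which(dt > 1.5 * cad)
    if (length(jump)) {
      starts <- c(starts, tt[jump] + cad)
      ends <- c(ends, tt[jump + 1L])
    }
  }
  if (!length(starts))
    return(data.frame(gap_start = series$times[0], gap_end = series$times[0]))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  ms <- starts[1]; me <- ends[1]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= me + 1e-9) {
      me <- max(me, ends[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- starts[i]; me <- ends[i]
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(
    gap_start = as.POSIXct(out_s, origin = "1970-01-01", tz = "UTC"),
    gap_end = as.POSIXct(out_e, origin = "1970-01-01", tz = "UTC"))
}
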