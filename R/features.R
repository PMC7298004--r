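fnv_hash <- function(x) {
  s <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 5381
  for (b in s) h <- (h * 31 + b) %% 1e9
  sprintf("%09.0f", h)
}

new_feature_vector <- function(values, strategy, shape, window = NULL,
                               cfg = NULL) {
  stopifnot(all(is.finite(values)), prod(shape) == length(values))
  structure(as.numeric(values), class = "feature_vector",
            strategy = strategy, shape_record = as.integer(shape),
            window = window, config_hash = fnv_hash(cfg))
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> strategy %s, length %d (shape %s)\n",
              attr(x, "strategy"), length(x),
              paste(attr(x, "shape_record"), collapse = "x")))
  invisible(x)
}

#' Instantaneous-spectrum feature
#'
#' The feature of the instantaneous classification strategy: the spectrum is
#' cropped to \code{[f_lo, f_hi]}, normalised with respect to its own mean
#' (divide by the mean by default, making the feature invariant to overall
#' gain), and optionally log10-transformed to scale up minute differences
#' between spectra.
#'
#' @param frame a \code{spectrum_frame} with \code{quality = "ok"}.
#' @param f_lo,f_hi crop band in Hz (default 18-800: sub-18 Hz wind noise is
#'   systematically excluded).
#' @param log_scale apply log10 after normalisation (default TRUE).
#' @param normalise \code{"divide"} (default), \code{"subtract"} or
#'   \code{"none"}.
#' @return A \code{feature_vector} (strategy \code{"instantaneous"}).
#' @export
instantaneous_feature <- function(frame, f_lo = 18, f_hi = 800,
                                  log_scale = TRUE,
                                  normalise = c("divide", "subtract",
                                                "none")) {
  stopifnot(inherits(frame, "spectrum_frame"))
  normalise <- match.arg(normalise)
  if (frame$quality != "ok") stop("cannot featurise a missing frame")
  fr <- crop_bandwidth(frame, f_lo, f_hi)
  v <- fr$amplitudes
  v <- switch(normalise, divide = v / mean(v), subtract = v - mean(v),
              none = v)
  if (log_scale) {
    if (any(v <= 0))
      stop("log transform requires strictly positive amplitudes")
    v <- log10(v)
  }
  new_feature_vector(v, "instantaneous", length(v),
                     window = format(frame$timestamp),
                     cfg = list(f_lo, f_hi, log_scale, normalise))
}

window_frames <- function(series, day, window) {
  t0 <- as.POSIXct(paste(format(day), "00:00:00"), tz = "UTC")
  which(series$times >= t0 + window[1] * 3600 &
          series$times < t0 + window[2] * 3600)
}

#' Is a day's analysis window usable?
#'
#' A day is usable when at least \code{min_ok} of its nominal window frames
#' are present and flagged \code{ok}; sparser days (power cuts) are excluded
#' from spectral-evolution analysis.
#'
#' @param series a \code{spectra_series}.
#' @param day a \code{Date}.
#' @param window numeric length 2, hours (default the midnight-5 AM night
#'   window).
#' @param min_ok minimum usable fraction of frames.
#' @return Logical scalar.
#' @export
day_usable <- function(series, day, window = c(0, 5), min_ok = 0.9) {
  idx <- window_frames(series, day, window)
  expected <- (window[2] - window[1]) * 3600 / series$cadence
  sum(series$quality[idx] == "ok") >= min_ok * expected
}

#' Intra-day two-dimensional Fourier transform
#'
#' For every vibration-frequency bin, the one-sided discrete-Fourier
#' magnitude of its time course across the \code{T} frames of the day's
#' analysis window, scaled by \code{1/T} so that modulation bin 0 equals the
#' time-mean amplitude.  Magnitudes carry no phase, so the image is
#' invariant to circular shifts of the frame order: the feature captures
#' how the spectrum modulated within the window without keeping the
#' absolute timings.  Occasional missing frames (up to 10 percent of the
#' window) are linearly interpolated in time per bin.
#'
#' @inheritParams day_usable
#' @return An object of class \code{image_2dft}: list with
#'   \code{magnitudes} (frequency bins by \code{floor(T/2)+1} modulation
#'   bins), \code{day}, \code{grid}, \code{n_frames}.
#' @export
daily_2dft <- function(series, day, window = c(0, 5)) {
  stopifnot(inherits(series, "spectra_series"))
  day <- as.Date(day)
  if (!day_usable(series, day, window))
    stop("day ", format(day), " is unusable: too many missing frames")
  idx <- window_frames(series, day, window)
  X <- series$amplitudes[idx, , drop = FALSE]
  miss <- series$quality[idx] != "ok"
  if (any(miss)) {
    tnum <- as.numeric(series$times[idx])
    for (b in seq_len(ncol(X)))
      X[miss, b] <- stats::approx(tnum[!miss], X[!miss, b], tnum[miss],
                                  rule = 2)$y
  }
  Tn <- nrow(X)
  n_mod <- floor(Tn / 2) + 1L
  mag <- t(abs(stats::mvfft(X))[seq_len(n_mod), , drop = FALSE]) / Tn
  structure(list(magnitudes = mag, day = day, grid = series$grid,
                 n_frames = Tn),
            class = "image_2dft")
}

#' Across-day three-dimensional Fourier transform
#'
#' Given the 2DFT images of \code{D} consecutive days, computes per pixel
#' the one-sided DFT magnitude of its across-day series, scaled by
#' \code{1/D}.  The result summarises how the intra-day modulation pattern
#' itself evolved over the preceding days, again without keeping absolute
#' timings.  With the default 10-day history the across-day axis has 6 bins
#' spanning 0 to 0.5 cycles/day (3.5 repetitions per week).
#'
#' @param images list of \code{image_2dft} for consecutive days, oldest
#'   first.
#' @return An object of class \code{tensor_3dft}: list with
#'   \code{magnitudes} (frequency x intra-day modulation x across-day
#'   modulation), \code{end_day}, \code{history_days}, \code{grid}.
#' @export
evolution_3dft <- function(images) {
  D <- length(images)
  if (D < 2L) stop("need at least 2 consecutive daily images")
  stopifnot(all(vapply(images, inherits, TRUE, "image_2dft")))
  days <- as.Date(vapply(images, function(i) format(i$day), character(1)))
  if (any(diff(as.numeric(days)) != 1))
    stop("daily images must cover consecutive days")
  dims <- dim(images[[1]]$magnitudes)
  if (!all(vapply(images, function(i)
    identical(dim(i$magnitudes), dims), TRUE)))
    stop("daily images must share one shape")
  stack <- vapply(images, function(i) i$magnitudes,
                  matrix(0, dims[1], dims[2]))      # B x M x D
  n_cross <- floor(D / 2) + 1L
  flat <- matrix(stack, nrow = dims[1] * dims[2], ncol = D)
  ft <- abs(stats::mvfft(t(flat)))[seq_len(n_cross), , drop = FALSE] / D
  mag <- array(t(ft), dim = c(dims[1], dims[2], n_cross))
  structure(list(magnitudes = mag, end_day = days[D], history_days = D,
                 grid = images[[1]]$grid),
            class = "tensor_3dft")
}

#' Flatten a 2DFT image or 3DFT tensor into a feature vector
#'
#' Row-major (C-order) flattening with the original shape recorded, so
#' \code{devectorize} inverts it exactly.
#'
#' @param x an \code{image_2dft}, \code{tensor_3dft}, matrix or array.
#' @param strategy strategy tag recorded on the result.
#' @return A \code{feature_vector}.
#' @export
vectorize <- function(x, strategy = "evolution") {
  mag <- if (inherits(x, c("image_2dft", "tensor_3dft"))) x$magnitudes
  else x
  d <- dim(mag)
  if (is.null(d)) d <- length(mag)
  v <- as.vector(aperm(array(mag, d), rev(seq_along(d))))
  win <- if (inherits(x, "tensor_3dft")) format(x$end_day)
  else if (inherits(x, "image_2dft")) format(x$day) else NULL
  new_feature_vector(v, strategy, d, window = win, cfg = d)
}

#' @rdname vectorize
#' @param v a \code{feature_vector} produced by \code{vectorize}.
#' @export
devectorize <- function(v) {
  shape <- attr(v, "shape_record")
  aperm(array(as.numeric(v), rev(shape)), rev(seq_along(shape)))
}

#' Mean-normalise a flattened evolution feature
#'
#' Both strategies normalise their linear feature arrays with respect to
#' their mean; the evolution strategy applies no log transform.
#'
#' @param tensor a \code{tensor_3dft} (or \code{image_2dft}).
#' @param normalise \code{"divide"} (default) or \code{"subtract"}.
#' @return A \code{feature_vector}.
#' @export
evolution_feature <- function(tensor, normalise = c("divide", "subtract")) {
  normalise <- match.arg(normalise)
  v <- vectorize(tensor)
  vals <- switch(normalise, divide = v / mean(v), subtract = v - mean(v))
  attributes(vals) <- attributes(v)
  vals
}
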