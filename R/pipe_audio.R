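#' Queen-pipe signal specification
#'
#' Parametric description of a single queen piping event.  A toot is a
#' ~1-second narrowband pipe followed by a train of short (~0.2 s) pulses
#' at the same fundamental; a quack is a longer series of ~0.2 s pulses
#' with much stronger (U-shaped) frequency modulation at a lower
#' fundamental, with no long leading pipe.
#'
#' @param kind \code{"toot"} or \code{"quack"}.
#' @param fundamental fundamental frequency in Hz (toots are usually seen
#'   near 400 Hz, quacks near 300 Hz).
#' @param pipe_duration seconds of the long leading pipe (toot only).
#' @param n_pulses number of short pulses (toot default 8, quack default 12).
#' @param pulse_duration seconds per pulse.
#' @param fm_depth Hz of U-shaped frequency modulation within each pulse.
#' @param start_time optional POSIXct onset, carried as metadata.
#' @return An object of class \code{pipe_spec}.
#' @export
pipe_spec <- function(kind = c("toot", "quack"), fundamental = 400,
                      pipe_duration = 1.0, n_pulses = NULL,
                      pulse_duration = 0.2,
                      fm_depth = NULL, start_time = NULL) {
  kind <- match.arg(kind)
  if (is.null(n_pulses)) n_pulses <- if (kind == "toot") 8L else 12L
  if (is.null(fm_depth)) fm_depth <- if (kind == "toot") 5 else 40
  if (pipe_duration <= 0 || pulse_duration <= 0)
    stop("durations must be positive")
  if (kind == "quack" && n_pulses < 10)
    stop("a quack is a long series of pulses (n_pulses >= 10)")
  structure(list(kind = kind, fundamental = fundamental,
                 pipe_duration = if (kind == "toot") pipe_duration else 0,
                 n_pulses = as.integer(n_pulses),
                 pulse_duration = pulse_duration, fm_depth = fm_depth,
                 start_time = start_time),
            class = "pipe_spec")
}

# one tone segment with raised-cosine edges and U-shaped FM
pipe_tone <- function(f0, dur, fs, fm_depth) {
  nsamp <- max(round(dur * fs), 2L)
  tau <- (seq_len(nsamp) - 0.5) / nsamp
  finst <- f0 + fm_depth * ((2 * tau - 1)^2 - 1 / 3)
  phase <- 2 * pi * cumsum(finst) / fs
  env <- rep(1, nsamp)
  ne <- max(round(0.01 * fs), 1L)
  if (2L * ne < nsamp) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ne) / ne))
    env[seq_len(ne)] <- ramp
    env[nsamp + 1L - seq_len(ne)] <- rev(ramp)
  }
  sin(phase) * env
}

#' Synthesise a queen-pipe waveform
#'
#' Renders a \code{pipe_spec} at audio rate: a toot is a long narrowband
#' pipe, a 0.15 s silence, then \code{n_pulses} short pulses at the same
#' fundamental separated by 0.1 s silences; a quack is a train of strongly
#' frequency-modulated pulses separated by 0.15 s silences.  White Gaussian
#' noise is added at \code{snr_db} (signal power measured over the voiced
#' samples); use \code{snr_db = Inf} for a clean waveform.
#'
#' @param spec a [pipe_spec()].
#' @param sample_rate Hz; must be at least four times the fundamental.
#' @param snr_db signal-to-noise ratio in dB.
#' @return Numeric waveform with attributes \code{sample_rate} and
#'   \code{segments} (a data frame of voiced segment start/end times and
#'   segment kind, usable as ground truth).
#' @export
synthesize_pipe_audio <- function(spec, sample_rate = 4096, snr_db = Inf) {
  stopifnot(inherits(spec, "pipe_spec"))
  if (sample_rate < 4 * spec$fundamental)
    stop("sample_rate must be at least 4x the fundamental (Nyquist margin)")
  fs <- sample_rate
  gap_len <- if (spec$kind == "toot") 0.1 else 0.15
  segs <- list(); wave <- numeric(0); cursor <- 0
  push <- function(x, kind) {
    t0 <- cursor
    wave <<- c(wave, x)
    cursor <<- cursor + length(x) / fs
    segs[[length(segs) + 1L]] <<-
      data.frame(start = t0, end = cursor, kind = kind)
  }
  silence <- function(dur) {
    wave <<- c(wave, numeric(round(dur * fs)))
    cursor <<- cursor + round(dur * fs) / fs
  }
  silence(0.2)
  if (spec$kind == "toot") {
    push(pipe_tone(spec$fundamental, spec$pipe_duration, fs, 2), "pipe")
    silence(0.15)
  }
  for (i in seq_len(spec$n_pulses)) {
    push(pipe_tone(spec$fundamental, spec$pulse_duration, fs,
                   spec$fm_depth), "pulse")
    if (i < spec$n_pulses) silence(gap_len)
  }
  silence(0.2)
  if (is.finite(snr_db)) {
    voiced <- logical(length(wave))
    for (s in segs)
      voiced[max(1, round(s$start * fs)):min(length(wave),
                                             round(s$end * fs))] <- TRUE
    rms <- sqrt(mean(wave[voiced]^2))
    wave <- wave + stats::rnorm(length(wave), 0,
                                rms / 10^(snr_db / 20))
  }
  structure(wave, sample_rate = fs, segments = do.call(rbind, segs))
}
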