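#' Short-time spectrogram of an audio-rate waveform
#'
#' Frames the waveform (rectangular window), takes the one-sided DFT
#' magnitude of each frame, and returns the time-frequency magnitude
#' matrix.  With non-overlapping frames the squared magnitudes satisfy
#' Parseval's identity against the time-domain energy.
#'
#' @param waveform numeric vector; \code{sample_rate} is read from its
#'   attribute unless given.
#' @param frame_len frame length in seconds (default 0.05, resolving 0.2 s
#'   pipe pulses with several frames).
#' @param hop hop between frame starts in seconds (default 0.01); must be
#'   positive and below \code{frame_len}... equal hops give exact tiling.
#' @param sample_rate Hz.
#' @return An object of class \code{hive_spectrogram}: list with
#'   \code{magnitudes} (frequency x time), \code{freqs} (Hz),
#'   \code{times} (frame centres, s), \code{n_fft}, \code{sample_rate}.
#' @export
compute_spectrogram <- function(waveform, frame_len = 0.05, hop = 0.01,
                                sample_rate = attr(waveform,
                                                   "sample_rate")) {
  if (is.null(sample_rate)) stop("sample_rate is required")
  if (!(frame_len > hop && hop > 0) && !(frame_len == hop))
    stop("need frame_len >= hop > 0")
  nf <- round(frame_len * sample_rate)
  nh <- max(round(hop * sample_rate), 1L)
  x <- as.numeric(waveform)
  if (length(x) < nf) stop("waveform shorter than one frame")
  starts <- seq(1L, length(x) - nf + 1L, by = nh)
  X <- vapply(starts, function(s) x[s:(s + nf - 1L)], numeric(nf))
  n_keep <- floor(nf / 2) + 1L
  mag <- abs(stats::mvfft(X))[seq_len(n_keep), , drop = FALSE]
  structure(list(magnitudes = mag,
                 freqs = (seq_len(n_keep) - 1) * sample_rate / nf,
                 times = (starts - 1 + nf / 2) / sample_rate,
                 n_fft = nf, sample_rate = sample_rate),
            class = "hive_spectrogram")
}

#' @export
print.hive_spectrogram <- function(x, ...) {
  cat(sprintf("<hive_spectrogram> %d freq bins x %d frames, 0-%g Hz\n",
              nrow(x$magnitudes), ncol(x$magnitudes), max(x$freqs)))
  invisible(x)
}

median3 <- function(v) {
  if (length(v) < 3L) return(v)
  out <- v
  for (i in 2:(length(v) - 1L)) out[i] <- stats::median(v[(i - 1):(i + 1)])
  out
}

#' Detect queen toots and quacks in a spectrogram
#'
#' Segments narrowband ridge energy in the queen-pipe band into voiced
#' units, groups units into events, and classifies each event using the
#' cues in priority order: a long (>= \code{min_pipe_s}) leading narrowband
#' pipe followed by short pulses at the same fundamental is a toot; a pulse
#' train with no long pipe is a quack (quacks are much more severely
#' frequency-modulated and sit lower in frequency, which the returned
#' \code{fm_depth} and \code{mean_fundamental} record).  Voicing uses the
#' ratio of the in-band peak to the in-band median magnitude, so detection
#' is invariant to overall spectrogram gain.
#'
#' @param spg a \code{hive_spectrogram} covering at least 150-600 Hz.
#' @param band candidate fundamental band, Hz.
#' @param voicing_ratio peak/median magnitude ratio declaring a frame
#'   voiced.
#' @param min_pipe_s minimum duration of the long leading pipe.
#' @param unit_gap_s silences shorter than this stay within one unit.
#' @param event_gap_s silences shorter than this keep units in one event.
#' @param min_unit_s discard isolated blips shorter than this.
#' @return Data frame of class \code{pipe_events} with columns
#'   \code{kind}, \code{start}, \code{end}, \code{mean_fundamental},
#'   \code{n_pulses}, \code{fm_depth}; fundamental tracks are attached as
#'   the \code{tracks} attribute (one data frame of time/Hz per event).
#' @export
detect_pipes <- function(spg, band = c(200, 550), voicing_ratio = 4,
                         min_pipe_s = 0.7, unit_gap_s = 0.05,
                         event_gap_s = 0.5, min_unit_s = 0.1) {
  stopifnot(inherits(spg, "hive_spectrogram"))
  if (min(spg$freqs) > 150 || max(spg$freqs) < 600)
    stop("spectrogram must cover 150-600 Hz")
  inb <- which(spg$freqs >= band[1] & spg$freqs <= band[2])
  sub <- spg$magnitudes[inb, , drop = FALSE]
  peak <- apply(sub, 2, max)
  med <- apply(sub, 2, stats::median)
  voiced <- peak > voicing_ratio * pmax(med, .Machine$double.eps)
  fund <- rep(NA_real_, length(voiced))
  fund[voiced] <- spg$freqs[inb][apply(sub[, voiced, drop = FALSE],
                                       2, which.max)]
  fund[voiced] <- median3(fund[voiced])
  dt <- if (length(spg$times) > 1) diff(spg$times[1:2]) else 0.01

  empty <- data.frame(kind = character(), start = numeric(),
                      end = numeric(), mean_fundamental = numeric(),
                      n_pulses = integer(), fm_depth = numeric())
  class(empty) <- c("pipe_events", "data.frame")
  if (!any(voiced)) return(empty)

  # voiced runs -> units (merge across sub-unit_gap holes)
  vi <- which(voiced)
  brk <- c(TRUE, diff(spg$times[vi]) > unit_gap_s + dt / 2)
  unit_id <- cumsum(brk)
  units <- do.call(rbind, lapply(split(vi, unit_id), function(ix)
    data.frame(start = spg$times[ix[1]] - dt / 2,
               end = spg$times[ix[length(ix)]] + dt / 2,
               f = mean(fund[ix]),
               fm = max(fund[ix]) - min(fund[ix]))))
  units <- units[units$end - units$start >= min_unit_s / 2, , drop = FALSE]
  if (!nrow(units)) return(empty)

  ev_id <- cumsum(c(TRUE, units$start[-1] - units$end[-nrow(units)] >
                      event_gap_s))
  rows <- lapply(split(seq_len(nrow(units)), ev_id), function(ix) {
    u <- units[ix, , drop = FALSE]
    durs <- u$end - u$start
    long_pipe <- durs[1] >= min_pipe_s
    if (!long_pipe && nrow(u) < 2L) return(NULL)  # isolated blip
    kind <- if (long_pipe) "toot" else "quack"
    n_pulses <- if (long_pipe) nrow(u) - 1L else nrow(u)
    data.frame(kind = kind, start = u$start[1], end = u$end[nrow(u)],
               mean_fundamental = mean(u$f), n_pulses = n_pulses,
               fm_depth = mean(u$fm))
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  tracks <- lapply(seq_len(nrow(out)), function(i) {
    sel <- vi[spg$times[vi] >= out$start[i] & spg$times[vi] <= out$end[i]]
    data.frame(time = spg$times[sel], hz = fund[sel])
  })
  attr(out, "tracks") <- tracks
  class(out) <- c("pipe_events", "data.frame")
  out
}

#' Hourly toot/quack presence in averaged-spectra series
#'
#' Queen pipes are visible in 3-minute averaged spectra as narrow ridges.
#' For each hour of the day this flags ridge energy in the toot band
#' (350-550 Hz) and the quack band (200-370 Hz, excluding the 250 Hz buzz
#' harmonic) whose log-amplitude excess over a matched baseline (the
#' per-bin median of the same hour across the preceding days), relative to
#' the band's median excess, exceeds \code{min_excess} decades.  The
#' band-median subtraction makes the flags invariant to broadband diurnal
#' amplitude changes and to overall gain.
#'
#' @param series a \code{spectra_series} whose grid reaches 600 Hz.
#' @param day a \code{Date}.
#' @param baseline_days how many preceding days form the baseline.
#' @param min_excess decades of relative log-amplitude excess.
#' @return Data frame with columns \code{hour}, \code{toot}, \code{quack}
#'   (logical; NA for hours with no data).
#' @export
pipe_presence_daily <- function(series, day, baseline_days = 3,
                                min_excess = 0.25) {
  stopifnot(inherits(series, "spectra_series"))
  f <- grid_freqs(series$grid)
  if (max(f) < 600) stop("series grid must reach 600 Hz")
  day <- as.Date(day)
  toot_bins <- which(f >= 350 & f <= 550)
  quack_bins <- which(f >= 200 & f <= 370 & abs(f - 250) > 15)
  prev <- day - seq_len(baseline_days)
  prev <- prev[prev >= as.Date(format(min(series$times)))]
  score_band <- function(hour_amp, base_amp, bins) {
    ex <- log10(pmax(hour_amp[bins], 1e-12)) -
      log10(pmax(base_amp[bins], 1e-12))
    max(ex - stats::median(ex))
  }
  res <- lapply(0:23, function(h) {
    cur <- hourly_average(series, day, h, h + 1)
    if (cur$quality != "ok")
      return(data.frame(hour = h, toot = NA, quack = NA))
    base <- if (length(prev)) {
      mats <- lapply(prev, function(d) {
        fr <- hourly_average(series, d, h, h + 1)
        if (fr$quality == "ok") fr$amplitudes else NULL
      })
      mats <- mats[!vapply(mats, is.null, TRUE)]
      if (length(mats)) apply(do.call(rbind, mats), 2, stats::median)
      else NULL
    } else NULL
    if (is.null(base)) {
      night <- window_frames(series, day, c(0, 5))
      okn <- night[series$quality[night] == "ok"]
      if (!length(okn))
        return(data.frame(hour = h, toot = NA, quack = NA))
      base <- apply(series$amplitudes[okn, , drop = FALSE], 2,
                    stats::median)
    }
    data.frame(hour = h,
               toot = score_band(cur$amplitudes, base, toot_bins) >
                 min_excess,
               quack = score_band(cur$amplitudes, base, quack_bins) >
                 min_excess)
  })
  do.call(rbind, res)
}

#' Pair pipe onsets/cessations of an event log into intervals
#'
#' @param log an \code{event_log}.
#' @return Data frame with columns \code{kind}, \code{start}, \code{end}.
#' @export
pipes_from_log <- function(log) {
  out <- list()
  for (k in c("toot", "quack")) {
    on <- sort(log$time[log$kind == paste0(k, "_onset")])
    off <- sort(log$time[log$kind == paste0(k, "_cessation")])
    m <- min(length(on), length(off))
    if (m)
      out[[k]] <- data.frame(kind = k, start = on[seq_len(m)],
                             end = off[seq_len(m)])
  }
  if (!length(out))
    return(data.frame(kind = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC")))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$start), , drop = FALSE]
}

#' Check queen-pipe chronology against colony events
#'
#' Evaluates the chronology rules observed in undisturbed colonies:
#' \describe{
#'   \item{toot_before_quack}{the first toot precedes the first quack.}
#'   \item{toot_delay_4_7d}{the first toot onset falls 4-7 days after the
#'     primary swarm exit (earlier onsets indicate disturbance, e.g. the
#'     early release of a gyne after a hive opening).}
#'   \item{toot_ceases_at_afterswarm}{tooting in progress at each
#'     afterswarm exit stops within the grace window (an emerged virgin
#'     queen leaves with the swarm).}
#' }
#' Each check returns pass/fail/not-applicable with evidence times.  The
#' report is a pure function of the inputs: record order does not matter.
#'
#' @param pipes data frame with \code{kind}, \code{start}, \code{end}
#'   (e.g. from [pipes_from_log()] or a detection pass).
#' @param log an \code{event_log} containing the swarm events.
#' @param grace_hours tolerance for cessation at an afterswarm.
#' @return A data frame with columns \code{check}, \code{status}
#'   (\code{"pass"}, \code{"fail"}, \code{"not_applicable"}) and
#'   \code{evidence}.
#' @export
pipe_chronology <- function(pipes, log, grace_hours = 6) {
  pipes <- pipes[order(pipes$start), , drop = FALSE]
  toots <- pipes[pipes$kind == "toot", , drop = FALSE]
  quacks <- pipes[pipes$kind == "quack", , drop = FALSE]
  swarm <- if (nrow(log)) log$time[log$kind == "primary_swarm"] else
    as.POSIXct(character(), tz = "UTC")
  afters <- if (nrow(log)) log$time[log$kind == "afterswarm"] else
    as.POSIXct(character(), tz = "UTC")
  fmt <- function(t) format(t, "%Y-%m-%d %H:%M")

  if (!nrow(toots) || !nrow(quacks)) {
    r1 <- list("not_applicable", "needs both toots and quacks")
  } else if (min(toots$start) < min(quacks$start)) {
    r1 <- list("pass", sprintf("first toot %s < first quack %s",
                               fmt(min(toots$start)),
                               fmt(min(quacks$start))))
  } else {
    r1 <- list("fail", sprintf("first quack %s precedes first toot %s",
                               fmt(min(quacks$start)),
                               fmt(min(toots$start))))
  }

  if (!length(swarm) || !nrow(toots)) {
    r2 <- list("not_applicable", "needs a primary swarm and toots")
  } else {
    delay <- as.numeric(difftime(min(toots$start), min(swarm),
                                 units = "days"))
    ok <- delay >= 4 && delay <= 7
    r2 <- list(if (ok) "pass" else "fail",
               sprintf("first toot %.1f days after primary swarm", delay))
  }

  if (!length(afters) || !nrow(toots)) {
    r3 <- list("not_applicable", "needs afterswarms and toots")
  } else {
    grace <- grace_hours * 3600
    bad <- vapply(afters, function(a) {
      any(toots$start < a & toots$end > a + grace)
    }, logical(1))
    r3 <- if (any(bad))
      list("fail", sprintf("tooting continues past afterswarm %s",
                           fmt(afters[which(bad)[1]])))
    else list("pass", "tooting stops at every afterswarm")
  }

  data.frame(check = c("toot_before_quack", "toot_delay_4_7d",
                       "toot_ceases_at_afterswarm"),
             status = c(r1[[1]], r2[[1]], r3[[1]]),
             evidence = c(r1[[2]], r2[[2]], r3[[2]]))
}

#' Detect swarm lift-off and failed-return signatures
#'
#' A swarm exit appears as a high-amplitude broadband transient centred
#' near 60 Hz at lift-off; a successful exit is followed by a sustained
#' drop of the 100-300 Hz buzz amplitude (half the colony has left), while
#' a failed swarm (clipped queen) re-enters, producing a ~150 Hz peak and
#' a short amplitude increase instead.
#'
#' @param series a \code{spectra_series} whose grid covers 30-300 Hz.
#' @param transient_excess decades by which the 45-75 Hz band must exceed
#'   the 30-42 Hz reference band (a contrast that cancels broadband
#'   diurnal amplitude swings) to declare a transient.
#' @param drop_ratio post-event buzz amplitude, relative to the same clock
#'   window of the previous day, below which the event is a lift-off.
#' @param peak150_excess decades of 140-160 Hz excess declaring a failed
#'   return.
#' @return Data frame of class \code{swarm_events}: \code{kind}
#'   (\code{lift_off}/\code{failed_return}), \code{time},
#'   \code{transient_score}, \code{post_ratio}, \code{peak150_score}.
#' @export
detect_swarm_events <- function(series, transient_excess = 0.5,
                                drop_ratio = 0.85,
                                peak150_excess = 0.25) {
  stopifnot(inherits(series, "spectra_series"))
  f <- grid_freqs(series$grid)
  if (min(f) > 30 || max(f) < 300) stop("grid must cover 30-300 Hz")
  low <- which(f >= 45 & f <= 75)
  ref <- which(f >= 30 & f <= 42)
  buzz <- which(f >= 100 & f <= 300)
  fail_b <- which(f >= 140 & f <= 160)
  ok <- series$quality == "ok"
  tt <- as.numeric(series$times)
  Lb <- rowMeans(series$amplitudes[, low, drop = FALSE])
  Rb <- rowMeans(series$amplitudes[, ref, drop = FALSE])
  score <- log10(pmax(Lb, 1e-12) / pmax(Rb, 1e-12))
  base <- stats::median(score[ok])
  cand <- which(ok & score - base > transient_excess)
  empty <- data.frame(kind = character(), time = series$times[0],
                      transient_score = numeric(),
                      post_ratio = numeric(), peak150_score = numeric())
  class(empty) <- c("swarm_events", "data.frame")
  if (!length(cand)) return(empty)
  grp <- cumsum(c(TRUE, diff(tt[cand]) > 900))
  rows <- lapply(split(cand, grp), function(ix) {
    i0 <- ix[1]
    t_ev <- tt[i0]
    # compare the post-event window with the same clock window one day
    # earlier so the diurnal foraging cycle cancels
    post <- ok & tt > t_ev + 1800 & tt <= t_ev + 2.5 * 3600
    pre <- ok & tt > t_ev + 1800 - 86400 & tt <= t_ev + 2.5 * 3600 - 86400
    if (!any(pre))
      pre <- ok & tt >= t_ev - 3 * 3600 & tt < t_ev - 600
    if (!any(pre) || !any(post)) return(NULL)
    ratio <- mean(series$amplitudes[post, buzz]) /
      mean(series$amplitudes[pre, buzz])
    post2 <- ok & tt > t_ev + 360 & tt <= t_ev + 2 * 3600
    if (!any(post2)) post2 <- post
    spec_post <- colMeans(series$amplitudes[post2, , drop = FALSE])
    spec_pre <- colMeans(series$amplitudes[pre, , drop = FALSE])
    p150 <- log10(max(spec_post[fail_b]) /
                    max(stats::median(spec_pre[fail_b]), 1e-12))
    kind <- if (ratio < drop_ratio) "lift_off"
    else if (p150 > peak150_excess) "failed_return" else NA_character_
    if (is.na(kind)) return(NULL)
    data.frame(kind = kind, time = series$times[i0],
               transient_score = score[i0] - base,
               post_ratio = ratio, peak150_score = p150)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("swarm_events", "data.frame")
  out
}
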