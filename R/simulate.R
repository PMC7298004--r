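gaussf <- function(f, mu, sd) exp(-0.5 * ((f - mu) / sd)^2)

# SD of x*10^N(0,s) relative to x, for log-normal multiplicative noise
lognorm_sd_factor <- function(noise_sd) {
  s2 <- (noise_sd * log(10))^2
  sqrt(exp(s2) - 1) * exp(s2 / 2)
}

# linear 0..1 growth of the planted signature over the pre-swarm ramp
sig_progress <- function(times, swarm_time, ramp_days) {
  if (is.null(swarm_time)) return(rep(0, length(times)))
  p <- (as.numeric(times) - (as.numeric(swarm_time) - ramp_days * 86400)) /
    (ramp_days * 86400)
  p[p < 0] <- 0
  p[as.numeric(times) > as.numeric(swarm_time)] <- 0
  pmin(p, 1)
}

#' Simulate a colony season of averaged vibration spectra
#'
#' Generates a full season of 3-minute averaged spectra (480 frames per
#' day) with the statistical structure the swarm classifiers assume, plus
#' the matching ground-truth event log.  Spectra are synthesised directly in
#' the frequency domain: a smooth noise floor with a colony-specific tilt
#' and gain drawn once per colony, Gaussian-profile buzz peaks at 125 and
#' 250 Hz that are amplified and broadened during foraging hours,
#' multiplicative log-normal per-bin noise, random sub-18 Hz wind noise,
#' and, for swarming scenarios, the linear pre-swarm signature ramp at
#' \code{sig_freq} and its harmonics, a broadband ~60 Hz lift-off transient
#' at each swarm exit followed by a sustained buzz-amplitude drop, a
#' ~150 Hz re-entry peak plus short amplitude increase after failed swarms,
#' and narrow drifting ridges for every scheduled queen pipe.
#'
#' All random draws depend only on the seed, the season length and the grid,
#' never on the event schedule, so a swarming scenario and its matched
#' non-swarming twin (same seed) differ only by the deterministic planted
#' components.
#'
#' @param scenario a [hive_scenario()].
#' @return A list with elements \code{series} (a \code{spectra_series}) and
#'   \code{events} (an \code{event_log}).
#' @export
simulate_series <- function(scenario) {
  stopifnot(inherits(scenario, "hive_scenario"))
  sc <- scenario
  n_days <- as.integer(as.numeric(sc$season_end - sc$season_start))
  t0 <- as.POSIXct(paste(format(sc$season_start), "00:00:00"), tz = "UTC")
  n <- n_days * 480L
  times <- t0 + (seq_len(n) - 1) * 180
  f <- grid_freqs(sc$grid)
  B <- length(f)

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(sc$rng_seed)

  # colony-level draws, then frame noise: order fixed and schedule-free
  tilt <- stats::rnorm(1, 0, 0.15)
  gain <- 10^stats::rnorm(1, 0, 0.15)
  eps <- matrix(stats::rnorm(n * B, 0, sc$noise_sd), n, B)
  gust <- stats::rexp(n)

  floor_col <- (1 + f / 50)^(-0.7) * exp(tilt * (f / 900 - 0.5))
  floor_at <- function(fq)
    (1 + fq / 50)^(-0.7) * exp(tilt * (fq / 900 - 0.5))

  hour <- (as.numeric(times) - as.numeric(t0)) %% 86400 / 3600
  forage <- hour >= sc$active_hours[1] & hour < sc$active_hours[2]

  buzz_night <- 5 * gaussf(f, sc$buzz_fund, 6) +
    2.5 * gaussf(f, sc$buzz_harm, 6)
  buzz_forage <- sc$forage_factor *
    (5 * gaussf(f, sc$buzz_fund, 15) + 2.5 * gaussf(f, sc$buzz_harm, 15)) +
    1.5 * exp(-((f - 200) / 200)^2)

  # buzz amplitude factor: sustained drop after each successful swarm exit,
  # brief increase after a failed (returned) swarm
  tt <- as.numeric(times)
  drop_fac <- rep(1, n)
  if (sc$swarming) {
    drop_fac[tt > as.numeric(sc$primary_swarm_time)] <- 0.55
    for (a in as.numeric(sc$afterswarm_times))
      drop_fac[tt > a] <- drop_fac[tt > a] * 0.85
    for (s in as.numeric(sc$failed_swarm_times)) {
      w <- tt > s & tt <= s + 2 * 3600
      drop_fac[w] <- drop_fac[w] * 1.3
    }
  }

  M <- outer(ifelse(forage, 2, 1), floor_col) +
    (drop_fac * ifelse(forage, 0, 1)) %o% buzz_night +
    (drop_fac * ifelse(forage, 1, 0)) %o% buzz_forage

  if (sc$swarming && sc$sig_gain > 0) {
    sdfac <- lognorm_sd_factor(sc$noise_sd)
    sig_shape <- rep(0, B)
    for (k in seq_len(sc$sig_harmonics)) {
      fk <- k * sc$sig_freq
      sig_shape <- sig_shape +
        (sc$sig_gain * sdfac * floor_at(fk) / k) * gaussf(f, fk, 3)
    }
    prog <- sig_progress(times, sc$primary_swarm_time, sc$ramp_days)
    M <- M + prog %o% sig_shape
  }

  # lift-off transients: high-amplitude burst peaking near 60 Hz on a
  # broadband pedestal, lasting ~6 minutes
  trans_shape <- 60 * gaussf(f, 60, 8) + 5 * exp(-f / 200)
  fail_shape <- 12 * gaussf(f, 150, 6)
  if (sc$swarming) {
    for (s in as.numeric(c(sc$primary_swarm_time, sc$afterswarm_times,
                           sc$failed_swarm_times))) {
      w <- which(tt >= s & tt < s + 360)
      if (length(w)) M[w, ] <- M[w, ] + rep(1, length(w)) %o% trans_shape
    }
    for (s in as.numeric(sc$failed_swarm_times)) {
      w <- which(tt > s & tt <= s + 2 * 3600)
      if (length(w)) M[w, ] <- M[w, ] + rep(1, length(w)) %o% fail_shape
    }
  }

  if (!is.null(sc$pipe_schedule) && nrow(sc$pipe_schedule)) {
    for (i in seq_len(nrow(sc$pipe_schedule))) {
      row <- sc$pipe_schedule[i, ]
      w <- which(tt >= as.numeric(row$start) & tt <= as.numeric(row$end))
      if (!length(w)) next
      frac <- (tt[w] - as.numeric(row$start)) /
        max(as.numeric(row$end) - as.numeric(row$start), 1)
      fi <- row$f_start + frac * (row$f_end - row$f_start)
      amp <- if (row$kind == "toot") 3.0 else 2.5
      sdr <- if (row$kind == "toot") 4 else 10
      for (j in seq_along(w))
        M[w[j], ] <- M[w[j], ] + amp * gaussf(f, fi[j], sdr)
    }
  }

  amp <- gain * M * 10^eps
  wb <- which(f < 18)
  if (length(wb))
    amp[, wb] <- amp[, wb] + (sc$wind_level * gust) %o% (1 / (1 + f[wb] / 4))

  quality <- rep("ok", n)
  events <- list()
  add_ev <- function(time, kind, note = "") {
    events[[length(events) + 1L]] <<-
      data.frame(time = time, kind = kind, note = note)
  }
  if (sc$swarming) {
    add_ev(sc$primary_swarm_time, "primary_swarm")
    for (a in sc$afterswarm_times |> as.list())
      add_ev(a, "afterswarm")
    for (s in sc$failed_swarm_times |> as.list())
      add_ev(s, "failed_swarm")
  }
  if (!is.null(sc$pipe_schedule) && nrow(sc$pipe_schedule)) {
    for (i in seq_len(nrow(sc$pipe_schedule))) {
      row <- sc$pipe_schedule[i, ]
      add_ev(row$start, paste0(row$kind, "_onset"))
      add_ev(row$end, paste0(row$kind, "_cessation"))
    }
  }
  if (!is.null(sc$power_cuts) && nrow(sc$power_cuts)) {
    for (i in seq_len(nrow(sc$power_cuts))) {
      w <- tt >= as.numeric(sc$power_cuts$start[i]) &
        tt < as.numeric(sc$power_cuts$end[i])
      quality[w] <- "missing"
      add_ev(sc$power_cuts$start[i], "power_cut_start")
      add_ev(sc$power_cuts$end[i], "power_cut_end")
    }
    amp[quality == "missing", ] <- NA_real_
  }

  ev <- if (length(events)) {
    all <- do.call(rbind, events)
    event_log(all$time, all$kind, all$note)
  } else event_log()
  list(series = spectra_series(sc$colony_id, times, sc$grid, amp, quality),
       events = ev)
}

#' Flag a window of a series as missing (power cut)
#'
#' Frames whose timestamps fall in \code{[start, end)} are flagged
#' \code{missing} and their amplitudes blanked; timestamps are retained so
#' downstream accounting sees an explicit gap, never zero spectra.
#'
#' @param series a \code{spectra_series}.
#' @param window POSIXct length-2 vector \code{c(start, end)}.
#' @return The modified \code{spectra_series}.
#' @export
inject_power_cut <- function(series, window) {
  stopifnot(inherits(series, "spectra_series"), length(window) == 2L)
  w <- series$times >= window[1] & series$times < window[2]
  if (!any(w)) return(series)
  series$quality[w] <- "missing"
  series$amplitudes[w, ] <- NA_real_
  series
}
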