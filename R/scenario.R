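#' Synthetic hive scenario
#'
#' Describes one synthetic colony season: the colony's baseline vibration
#' spectrum, its diurnal foraging cycle, and (for swarming colonies) the
#' timing of the primary swarm, afterswarms, failed swarming attempts, the
#' pre-swarm low-frequency signature ramp, and the queen-pipe schedule.
#'
#' The planted pre-swarm signature is a narrow spectral peak at
#' \code{sig_freq} (default 21 Hz, the band of the dorso-ventral abdominal
#' vibration signal that dominates real pre-swarm discriminant spectra) plus
#' \code{sig_harmonics - 1} harmonics, whose amplitude ramps linearly from
#' zero over the \code{ramp_days} days before the primary swarm up to
#' \code{sig_gain} times the night-time noise-floor standard deviation.
#' With \code{sig_gain = 0} the generator draws identically distributed
#' pre-swarm data for swarming and non-swarming colonies, which serves as
#' the null model in false-positive tests.
#'
#' @param colony_id colony name.
#' @param season_start,season_end \code{Date}s; frames cover
#'   \code{[season_start 00:00, season_end 00:00)}.
#' @param swarming logical; if \code{FALSE} all swarm-time arguments must be
#'   empty.
#' @param primary_swarm_time POSIXct exit time of the primary swarm.
#' @param afterswarm_times,failed_swarm_times POSIXct vectors.
#' @param sig_freq planted signature fundamental, Hz.
#' @param sig_harmonics number of signature peaks (fundamental included).
#' @param ramp_days days of linear pre-swarm signature growth.
#' @param sig_gain peak signature amplitude as a multiple of the night-time
#'   noise-floor standard deviation at \code{sig_freq}.
#' @param buzz_fund,buzz_harm colony buzz trace frequencies, Hz (the general
#'   buzzing of the bees sits at 125 Hz with an upper harmonic at 250 Hz).
#' @param active_hours numeric length 2, start/end hour of the foraging day.
#' @param forage_factor amplitude multiplier during foraging hours.
#' @param wind_level amplitude scale of the sub-18 Hz wind noise.
#' @param noise_sd per-bin multiplicative log-normal noise, in decades.
#' @param pipe_schedule data frame with columns \code{kind} (toot/quack),
#'   \code{start}, \code{end} (POSIXct) and \code{f_start}, \code{f_end}
#'   (Hz): each row is one continuous piping block rendered into the
#'   averaged spectra as a narrow ridge drifting from \code{f_start} to
#'   \code{f_end}.
#' @param power_cuts data frame with POSIXct columns \code{start},
#'   \code{end}.
#' @param grid \code{freq_grid} of the synthetic spectra.  The default
#'   covers 0-897 Hz at 3 Hz spacing; both classifiers crop at 800 Hz so the
#'   full 5.5 kHz hardware bandwidth would only inflate memory.
#' @param rng_seed integer seed; identical (scenario, seed) pairs yield
#'   byte-identical simulations.
#' @return An object of class \code{hive_scenario}.
#' @seealso [simulate_series()], [default_pipe_schedule()]
#' @export
hive_scenario <- function(colony_id = "colony-1",
                          season_start = as.Date("2014-04-01"),
                          season_end = season_start + 60,
                          swarming = FALSE,
                          primary_swarm_time = NULL,
                          afterswarm_times = NULL,
                          failed_swarm_times = NULL,
                          sig_freq = 21, sig_harmonics = 2,
                          ramp_days = 13, sig_gain = 3.0,
                          buzz_fund = 125, buzz_harm = 250,
                          active_hours = c(9, 16), forage_factor = 4,
                          wind_level = 2, noise_sd = 0.2,
                          pipe_schedule = NULL, power_cuts = NULL,
                          grid = freq_grid(0, 3, 300),
                          rng_seed = 1L) {
  stopifnot(inherits(season_start, "Date"), inherits(season_end, "Date"))
  if (as.numeric(season_end - season_start) < 1)
    stop("season length must be at least 1 day")
  if (ramp_days < 1) stop("ramp_days must be >= 1")
  if (sig_gain < 0) stop("sig_gain must be >= 0")
  if (!swarming) {
    if (!is.null(primary_swarm_time) || length(afterswarm_times) ||
        length(failed_swarm_times))
      stop("non-swarming scenarios must have empty swarm-time lists")
  } else {
    if (is.null(primary_swarm_time))
      stop("swarming scenarios need a primary_swarm_time")
  }
  span_ok <- function(t) is.null(t) || length(t) == 0L ||
    (min(t) >= as.POSIXct(paste(format(season_start), "00:00:00"),
                          tz = "UTC") &&
       max(t) < as.POSIXct(paste(format(season_end), "00:00:00"),
                           tz = "UTC"))
  if (!span_ok(primary_swarm_time) || !span_ok(afterswarm_times) ||
      !span_ok(failed_swarm_times))
    stop("swarm times must fall inside the season")
  if (!is.null(pipe_schedule) && nrow(pipe_schedule)) {
    stopifnot(all(c("kind", "start", "end", "f_start", "f_end") %in%
                    names(pipe_schedule)))
    toot <- pipe_schedule$kind == "toot"
    f_all <- c(pipe_schedule$f_start[toot], pipe_schedule$f_end[toot])
    if (length(f_all) && (min(f_all) < 200 || max(f_all) > 550))
      stop("toot fundamentals must lie within 200-550 Hz")
  }
  structure(list(
    colony_id = colony_id, season_start = season_start,
    season_end = season_end, swarming = swarming,
    primary_swarm_time = primary_swarm_time,
    afterswarm_times = afterswarm_times,
    failed_swarm_times = failed_swarm_times,
    sig_freq = sig_freq, sig_harmonics = as.integer(sig_harmonics),
    ramp_days = ramp_days, sig_gain = sig_gain,
    buzz_fund = buzz_fund, buzz_harm = buzz_harm,
    active_hours = active_hours, forage_factor = forage_factor,
    wind_level = wind_level, noise_sd = noise_sd,
    pipe_schedule = pipe_schedule, power_cuts = power_cuts,
    grid = grid, rng_seed = as.integer(rng_seed)),
    class = "hive_scenario")
}

#' @export
print.hive_scenario <- function(x, ...) {
  cat(sprintf("<hive_scenario> '%s' %s to %s, %s\n", x$colony_id,
              format(x$season_start), format(x$season_end),
              if (x$swarming) sprintf("swarming (%s)",
                                      format(x$primary_swarm_time))
              else "non-swarming"))
  invisible(x)
}

#' Natural queen-pipe schedule for a swarming scenario
#'
#' Builds a piping timetable that honours the chronology observed in
#' undisturbed colonies: tooting by the first emerged virgin queen starts
#' \code{toot_delay_days} (4-7 under natural conditions) after the primary
#' swarm, quacking by cell-captive gynes follows six hours later, tooting
#' ceases at each afterswarm exit and resumes three hours later when the
#' next gyne is released, and all piping stops at the final afterswarm.
#' Toot fundamentals rise across each block (the emerged queen's pipe
#' frequency increases with age); quacks rise from 280 to 350 Hz.
#'
#' @param primary_swarm_time POSIXct primary swarm exit.
#' @param afterswarm_times POSIXct vector of afterswarm exits (sorted).
#' @param toot_delay_days days between the primary swarm and the first toot.
#' @return A pipe-schedule data frame suitable for [hive_scenario()].
#' @export
default_pipe_schedule <- function(primary_swarm_time, afterswarm_times,
                                  toot_delay_days = 5) {
  t_on <- primary_swarm_time + toot_delay_days * 86400
  a <- sort(afterswarm_times)
  if (length(a) == 0L) a <- t_on + 4 * 86400
  bounds <- c(t_on, a)
  rows <- list()
  f_lo <- c(350, 400, 430, 450)
  for (i in seq_len(length(bounds) - 1L)) {
    s <- if (i == 1L) bounds[1] else bounds[i] + 3 * 3600
    e <- bounds[i + 1L]
    if (e <= s) next
    f0 <- f_lo[min(i, length(f_lo))]
    rows[[length(rows) + 1L]] <-
      data.frame(kind = "toot", start = s, end = e,
                 f_start = f0, f_end = 480)
  }
  rows[[length(rows) + 1L]] <-
    data.frame(kind = "quack", start = t_on + 6 * 3600, end = max(a),
               f_start = 280, f_end = 350)
  out <- do.call(rbind, rows)
  out[out$end > out$start, , drop = FALSE]
}

#' Read a scenario description from JSON or YAML
#'
#' Scalar fields use the same names as [hive_scenario()]; dates are ISO
#' \code{YYYY-MM-DD}, times ISO-8601 \code{YYYY-MM-DDTHH:MM:SS}.
#'
#' @param path a \code{.json}, \code{.yaml} or \code{.yml} file.
#' @return A \code{hive_scenario}.
#' @export
read_scenario <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  ptime <- function(x) if (is.null(x) || !length(x)) NULL else
    as.POSIXct(unlist(x), format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  args <- list(
    colony_id = cfg$colony_id %||% "colony-1",
    season_start = as.Date(cfg$season_start),
    season_end = as.Date(cfg$season_end),
    swarming = isTRUE(cfg$swarming),
    primary_swarm_time = ptime(cfg$primary_swarm_time),
    afterswarm_times = ptime(cfg$afterswarm_times),
    failed_swarm_times = ptime(cfg$failed_swarm_times),
    rng_seed = cfg$rng_seed %||% 1L)
  for (fld in c("sig_freq", "sig_harmonics", "ramp_days", "sig_gain",
                "buzz_fund", "buzz_harm", "forage_factor", "wind_level",
                "noise_sd"))
    if (!is.null(cfg[[fld]])) args[[fld]] <- cfg[[fld]]
  if (isTRUE(cfg$default_pipes) && args$swarming)
    args$pipe_schedule <- default_pipe_schedule(args$primary_swarm_time,
                                                args$afterswarm_times)
  do.call(hive_scenario, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
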