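# Small in-code fixtures shared across test files.

make_series <- function(n_frames = 40, n_bins = 10, amp = NULL,
                        start = as.POSIXct("2014-04-01 00:00:00",
                                           tz = "UTC"),
                        quality = "ok", cadence = 180) {
  g <- freq_grid(0, 3, n_bins)
  if (is.null(amp)) amp <- matrix(1, n_frames, n_bins)
  spectra_series("test", start + (seq_len(n_frames) - 1) * cadence, g,
                 amp, quality = quality, cadence = cadence)
}

# a short swarming scenario with the generator defaults
mini_swarm_scenario <- function(days = 20, swarm_day = 16, seed = 11,
                                sig_gain = 3.0, pipes = FALSE) {
  start <- as.Date("2014-04-01")
  s_time <- as.POSIXct(paste(format(start + swarm_day), "14:00:00"),
                       tz = "UTC")
  af <- s_time + c(9, 13) * 86400
  af <- af[af < as.POSIXct(paste(format(start + days), "00:00:00"),
                           tz = "UTC")]
  hive_scenario(colony_id = "mini-sw", season_start = start,
                season_end = start + days, swarming = TRUE,
                primary_swarm_time = s_time, afterswarm_times = af,
                sig_gain = sig_gain,
                pipe_schedule = if (pipes)
                  default_pipe_schedule(s_time, af) else NULL,
                rng_seed = seed)
}

mini_quiet_scenario <- function(days = 20, seed = 11) {
  start <- as.Date("2014-04-01")
  hive_scenario(colony_id = "mini-ns", season_start = start,
                season_end = start + days, swarming = FALSE,
                rng_seed = seed)
}

# hand-built alarm series for nightly-mean / lead-time tests
make_alarm <- function(criteria, start = as.POSIXct("2014-04-01 00:00:00",
                                                    tz = "UTC"),
                       threshold = 0.8) {
  hourly <- data.frame(
    time = start + (seq_along(criteria) - 1) * 3600,
    criterion = criteria, missing = is.na(criteria),
    triggered = !is.na(criteria) & criteria < threshold)
  structure(list(hourly = hourly, threshold = threshold,
                 strategy = "instantaneous"),
            class = "alarm_series")
}

# separable two-class feature fixture
separable_db <- function(n_per_class = 8, p = 12, gap = 4, seed = 5) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p, gap), n_per_class))
  list(x = x, labels = rep(c("PTS", "NS"), each = n_per_class))
}
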