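test_that("simulation is deterministic given (scenario, seed)", {
  sc <- mini_quiet_scenario(days = 3, seed = 21)
  a <- simulate_series(sc)
  b <- simulate_series(sc)
  expect_identical(a$series$amplitudes, b$series$amplitudes)
  expect_identical(a$series$times, b$series$times)
})

test_that("quiet nights carry the 125/250 Hz buzz as the top peaks above 100 Hz", {
  sim <- simulate_series(mini_quiet_scenario(days = 3, seed = 22))
  fr <- hourly_average(sim$series, as.Date("2014-04-02"), 2, 3)
  f <- grid_freqs(fr$grid)
  amp <- fr$amplitudes
  amp[f <= 100] <- -Inf
  p1 <- f[which.max(amp)]
  amp[abs(f - p1) <= 12] <- -Inf              # mask the first peak's flanks
  p2 <- f[which.max(amp)]
  top2 <- sort(c(p1, p2))
  expect_lt(abs(top2[1] - 125), 6)
  expect_lt(abs(top2[2] - 250), 6)
})

test_that("swarm lift-off peaks near 60 Hz and night amplitude drops after", {
  sc <- mini_swarm_scenario(days = 20, swarm_day = 10, seed = 23)
  sim <- simulate_series(sc)
  i <- which(sim$series$times == sc$primary_swarm_time)
  f <- grid_freqs(sim$series$grid)
  band <- f >= 30 & f <= 300
  expect_lt(abs(f[band][which.max(sim$series$amplitudes[i, band])] - 60),
            10)
  before <- hourly_average(sim$series, as.Date("2014-04-09"), 0, 5)
  after <- hourly_average(sim$series, as.Date("2014-04-13"), 0, 5)
  buzz <- f >= 100 & f <= 300
  expect_lt(mean(after$amplitudes[buzz]), mean(before$amplitudes[buzz]))
})

test_that("the planted signature follows the generator's linear ramp", {
  days <- 20; swarm_day <- 16
  sw <- simulate_series(mini_swarm_scenario(days, swarm_day, seed = 24))
  ns <- simulate_series(mini_quiet_scenario(days, seed = 24))
  sc <- mini_swarm_scenario(days, swarm_day, seed = 24)
  f <- grid_freqs(sw$series$grid)
  bin <- which.min(abs(f - sc$sig_freq))
  night_diff <- function(day_offset) {
    d <- as.Date("2014-04-01") + swarm_day + day_offset
    a <- hourly_average(sw$series, d, 0, 5)$amplitudes[bin]
    b <- hourly_average(ns$series, d, 0, 5)$amplitudes[bin]
    a - b
  }
  night_prog <- function(day_offset) {
    d <- as.POSIXct(paste(format(as.Date("2014-04-01") + swarm_day +
                                   day_offset), "02:30:00"), tz = "UTC")
    hivewatch:::sig_progress(d, sc$primary_swarm_time, sc$ramp_days)
  }
  # ratio of planted amplitudes between the last and an early ramp night
  # matches the ramp formula (the noise cancels exactly between the twins)
  expect_equal(night_diff(0) / night_diff(-10),
               night_prog(0) / night_prog(-10), tolerance = 0.15)
  # and the planted night amplitude is non-decreasing across the ramp
  diffs <- vapply(-12:0, night_diff, numeric(1))
  expect_gt(stats::cor(diffs, -12:0), 0.95)
})

test_that("sig_gain = 0 is a true null: pre-swarm data match the non-swarming twin", {
  sw <- simulate_series(mini_swarm_scenario(days = 10, swarm_day = 8,
                                            seed = 25, sig_gain = 0))
  ns <- simulate_series(mini_quiet_scenario(days = 10, seed = 25))
  pre <- sw$series$times < as.POSIXct("2014-04-08 00:00:00", tz = "UTC")
  expect_identical(sw$series$amplitudes[pre, ], ns$series$amplitudes[pre, ])
})

test_that("power-cut injection flags frames without deleting them", {
  sim <- simulate_series(mini_quiet_scenario(days = 4, seed = 26))
  w <- as.POSIXct(c("2014-04-02 00:00:00", "2014-04-03 00:00:00"),
                  tz = "UTC")
  cut <- inject_power_cut(sim$series, w)
  expect_equal(length(cut$times), length(sim$series$times))
  g <- scan_gaps(cut)
  expect_equal(nrow(g), 1L)
  expect_equal(g$gap_start, w[1])
  expect_equal(g$gap_end, w[2])
  same <- inject_power_cut(sim$series, c(w[1], w[1]))
  expect_identical(same$quality, sim$series$quality)
})

test_that("scenario invariants are enforced", {
  expect_error(hive_scenario(swarming = TRUE), "primary_swarm_time")
  expect_error(hive_scenario(
    swarming = FALSE,
    afterswarm_times = as.POSIXct("2014-05-01", tz = "UTC")),
    "empty swarm-time lists")
  expect_error(mini_swarm_scenario(days = 10, swarm_day = 40),
               "inside the season")
  expect_error(hive_scenario(sig_gain = -1), "sig_gain")
  bad <- data.frame(kind = "toot",
                    start = as.POSIXct("2014-04-02", tz = "UTC"),
                    end = as.POSIXct("2014-04-03", tz = "UTC"),
                    f_start = 600, f_end = 700)
  expect_error(hive_scenario(pipe_schedule = bad), "200-550")
})

test_that("toot audio has the published temporal structure", {
  w <- synthesize_pipe_audio(pipe_spec("toot", 400), snr_db = Inf)
  segs <- attr(w, "segments")
  # 1 s pipe + 8 pulses of 0.2 s of voiced material
  expect_equal(sum(segs$end - segs$start), 1.0 + 8 * 0.2, tolerance = 0.02)
  expect_equal(sum(segs$kind == "pulse"), 8)
  # envelope oracle: voiced fraction of the waveform agrees
  fs <- attr(w, "sample_rate")
  env <- stats::filter(abs(w), rep(1 / 64, 64), sides = 2)
  voiced_s <- sum(env > 0.25, na.rm = TRUE) / fs
  expect_equal(voiced_s, 2.6, tolerance = 0.1)
})

test_that("a single clean pulse peaks at the spec fundamental", {
  w <- synthesize_pipe_audio(pipe_spec("toot", 440, n_pulses = 1,
                                       pipe_duration = 1, fm_depth = 0),
                             sample_rate = 8192, snr_db = Inf)
  fs <- attr(w, "sample_rate")
  sp <- abs(stats::fft(as.numeric(w)))
  freqs <- (seq_along(sp) - 1) * fs / length(sp)
  half <- freqs <= fs / 2
  expect_lt(abs(freqs[half][which.max(sp[half])] - 440), 3)
})

test_that("a clean 12-pulse quack shows 12 envelope bursts", {
  w <- synthesize_pipe_audio(pipe_spec("quack", 300, n_pulses = 12),
                             snr_db = Inf)
  env <- stats::filter(abs(w), rep(1 / 64, 64), sides = 2)
  on <- !is.na(env) & env > max(env, na.rm = TRUE) / 2
  bursts <- sum(diff(c(FALSE, on)) == 1)
  expect_equal(bursts, 12)
})

test_that("pipe synthesis enforces the Nyquist margin", {
  expect_error(synthesize_pipe_audio(pipe_spec("toot", 400),
                                     sample_rate = 1000), "4x")
})
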