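test_that("the spectrogram localises tones and conserves energy", {
  fs <- 4096
  t <- seq(0, 2, length.out = 2 * fs)
  tone <- structure(sin(2 * pi * 400 * t), sample_rate = fs)
  spg <- compute_spectrogram(tone)
  ridge <- spg$freqs[apply(spg$magnitudes, 2, which.max)]
  expect_true(all(abs(ridge - 400) <= fs / spg$n_fft))

  silent <- structure(numeric(fs), sample_rate = fs)
  spg0 <- compute_spectrogram(silent)
  expect_equal(max(spg0$magnitudes), 0)

  # Parseval on white noise with exactly tiling frames
  set.seed(40)
  noise <- structure(stats::rnorm(fs), sample_rate = fs)
  spgn <- compute_spectrogram(noise, frame_len = 0.05, hop = 0.05)
  nf <- spgn$n_fft
  m <- spgn$magnitudes
  nyq <- nrow(m)
  e_freq <- sum(m[1, ]^2 + m[nyq, ]^2 + 2 * colSums(m[2:(nyq - 1), ]^2)) /
    nf
  covered <- length(spgn$times) * nf
  e_time <- sum(noise[seq_len(covered)]^2)
  expect_equal(e_freq, e_time, tolerance = 0.01)

  expect_error(compute_spectrogram(structure(numeric(10),
                                             sample_rate = fs)),
               "shorter than one frame")
})

test_that("toots and quacks are recovered with generator ground truth", {
  set.seed(41)
  w <- synthesize_pipe_audio(pipe_spec("toot", 400), snr_db = 10)
  ev <- detect_pipes(compute_spectrogram(w))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$kind, "toot")
  expect_lt(abs(ev$mean_fundamental - 400), 10)
  expect_equal(ev$n_pulses, 8L)

  wq <- synthesize_pipe_audio(pipe_spec("quack", 300, n_pulses = 12),
                              snr_db = 10)
  evq <- detect_pipes(compute_spectrogram(wq))
  expect_equal(nrow(evq), 1L)
  expect_equal(evq$kind, "quack")
  expect_equal(evq$n_pulses, 12L)
  expect_lt(abs(evq$mean_fundamental - 300), 10)
  # quacks are far more severely frequency modulated than toot pulses
  expect_gt(evq$fm_depth, 15)

  noise <- structure(stats::rnorm(4096 * 3), sample_rate = 4096)
  expect_equal(nrow(detect_pipes(compute_spectrogram(noise))), 0L)
})

test_that("pipe classification is invariant to overall gain", {
  set.seed(42)
  w <- synthesize_pipe_audio(pipe_spec("toot", 450), snr_db = 12)
  a <- detect_pipes(compute_spectrogram(w))
  spg <- compute_spectrogram(w)
  spg$magnitudes <- spg$magnitudes * 1e4
  b <- detect_pipes(spg)
  expect_equal(a$kind, b$kind)
  expect_equal(a$n_pulses, b$n_pulses)
  expect_equal(a$mean_fundamental, b$mean_fundamental)
})

test_that("detection stays sharp at 6 dB and degrades with falling SNR", {
  run_bench <- function(snr, n_events = 50, seed = 43) {
    set.seed(seed)
    kinds <- sample(c("toot", "quack"), n_events, replace = TRUE)
    hits <- 0; detections <- 0; correct <- 0
    for (i in seq_len(n_events)) {
      f0 <- if (kinds[i] == "toot") stats::runif(1, 360, 500) else
        stats::runif(1, 220, 340)
      spec <- pipe_spec(kinds[i], f0)
      ev <- detect_pipes(compute_spectrogram(
        synthesize_pipe_audio(spec, snr_db = snr)))
      detections <- detections + nrow(ev)
      if (nrow(ev)) {
        hits <- hits + 1
        if (ev$kind[1] == kinds[i] &&
            abs(ev$mean_fundamental[1] - f0) < 25)
          correct <- correct + 1
      }
    }
    recall <- correct / n_events
    precision <- if (detections) correct / detections else 1
    c(recall = recall, precision = precision)
  }
  at6 <- run_bench(6)
  expect_gte(at6["recall"], 0.9)
  expect_gte(at6["precision"], 0.9)
  at_minus6 <- run_bench(-6)
  at_minus14 <- run_bench(-14)
  f1 <- function(pr) 2 * pr[1] * pr[2] / max(pr[1] + pr[2], 1e-9)
  expect_gte(f1(at6), f1(at_minus6))
  expect_gte(f1(at_minus6), f1(at_minus14))
})

test_that("scheduled pipes are flagged in the right averaged-spectra bands", {
  start <- as.Date("2014-04-01")
  mk_sched <- function(kind, day, h0, h1, f0, f1) {
    data.frame(kind = kind,
               start = as.POSIXct(paste(format(start + day),
                                        sprintf("%02d:00:00", h0)),
                                  tz = "UTC"),
               end = as.POSIXct(paste(format(start + day),
                                      sprintf("%02d:00:00", h1)),
                                tz = "UTC"),
               f_start = f0, f_end = f1)
  }
  sched <- rbind(mk_sched("toot", 2, 6, 9, 420, 430),
                 mk_sched("quack", 2, 18, 21, 300, 310))
  sc <- hive_scenario(season_start = start, season_end = start + 4,
                      swarming = TRUE,
                      primary_swarm_time =
                        as.POSIXct(paste(format(start + 1), "14:00:00"),
                                   tz = "UTC"),
                      pipe_schedule = sched, rng_seed = 44)
  sim <- simulate_series(sc)
  pres <- pipe_presence_daily(sim$series, start + 2)
  expect_true(all(pres$toot[pres$hour %in% 6:8]))
  expect_false(any(pres$quack[pres$hour %in% 6:8]))
  expect_true(all(pres$quack[pres$hour %in% 18:20]))
  expect_false(any(pres$toot[pres$hour %in% 18:20]))
  # a clean day carries no flags at all
  quiet <- pipe_presence_daily(
    simulate_series(mini_quiet_scenario(days = 4, seed = 45))$series,
    start + 2)
  expect_false(any(quiet$toot, na.rm = TRUE))
  expect_false(any(quiet$quack, na.rm = TRUE))
})

test_that("chronology checks encode the natural piping sequence", {
  sc <- mini_swarm_scenario(days = 28, swarm_day = 10, seed = 46,
                            pipes = TRUE)
  sim <- simulate_series(sc)
  pipes <- pipes_from_log(sim$events)
  rep1 <- pipe_chronology(pipes, sim$events)
  expect_equal(rep1$status, rep("pass", 3))

  # permutation of record order changes nothing
  shuffled <- pipes[sample(nrow(pipes)), ]
  expect_equal(pipe_chronology(shuffled, sim$events), rep1)

  # a quack before any toot violates rule (a)
  early_quack <- pipes
  early_quack$start[early_quack$kind == "quack"][1] <-
    min(pipes$start) - 86400
  repa <- pipe_chronology(early_quack, sim$events)
  expect_equal(repa$status[1], "fail")

  # disturbed colony: tooting 2 days after the swarm violates rule (b)
  sw_time <- sim$events$time[sim$events$kind == "primary_swarm"][1]
  disturbed <- data.frame(kind = "toot", start = sw_time + 2 * 86400,
                          end = sw_time + 3 * 86400)
  repb <- pipe_chronology(disturbed, sim$events)
  expect_equal(repb$status[2], "fail")

  # no events at all: everything is not-applicable
  rep0 <- pipe_chronology(pipes[0, ], event_log())
  expect_equal(rep0$status, rep("not_applicable", 3))
})

test_that("lift-offs and failed returns are told apart from spectra", {
  sc <- mini_swarm_scenario(days = 16, swarm_day = 10, seed = 47)
  sim <- simulate_series(sc)
  ev <- detect_swarm_events(sim$series)
  lo <- ev[ev$kind == "lift_off", ]
  expect_gte(nrow(lo), 1L)
  expect_lte(min(abs(as.numeric(lo$time) -
                       as.numeric(sc$primary_swarm_time))), 360)

  st <- as.POSIXct("2014-04-11 14:00:00", tz = "UTC")
  scf <- hive_scenario(season_start = as.Date("2014-04-01"),
                       season_end = as.Date("2014-04-17"),
                       swarming = TRUE, primary_swarm_time = st,
                       failed_swarm_times = st - 2 * 86400, rng_seed = 48)
  simf <- simulate_series(scf)
  evf <- detect_swarm_events(simf$series)
  fail_day <- as.Date(format(evf$time)) == as.Date("2014-04-09")
  expect_true(any(evf$kind[fail_day] == "failed_return"))
  expect_false(any(evf$kind[fail_day] == "lift_off"))

  quiet <- simulate_series(mini_quiet_scenario(days = 10, seed = 49))
  expect_equal(nrow(detect_swarm_events(quiet$series)), 0L)
})
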