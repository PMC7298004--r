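#' Standard synthetic study cohort
#'
#' Builds the scenario set of the package's reference experiment:
#' \code{n_swarming} swarming and \code{n_nonswarming} non-swarming
#' colonies monitored over a 60-day season, with generator defaults
#' (21 Hz signature, 13-day ramp, gain 3 night-noise SDs).  Swarm days are
#' drawn between day 30 and day 45 of the season (exit between 12:00 and
#' 15:00), afterswarms follow 9 and 13 days later, and each swarming
#' colony gets a natural queen-pipe schedule with a toot delay of 4-7
#' days.  Colony simulation seeds are \code{(seed - 1) * 100 + 1:n}, so the
#' default cohort uses seeds 1..32.
#'
#' @param n_swarming,n_nonswarming cohort sizes.
#' @param season_start first day of the season.
#' @param days season length in days.
#' @param seed master seed for the cohort layout and colony seeds.
#' @param sig_gain planted signature gain (see [hive_scenario()]).
#' @return List of \code{hive_scenario} objects (swarming first).
#' @export
cohort_scenarios <- function(n_swarming = 18, n_nonswarming = 14,
                             season_start = as.Date("2014-04-01"),
                             days = 60, seed = 1, sig_gain = 3.0) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed((seed - 1) %% 19997 * 1000 + 999)
  n <- n_swarming + n_nonswarming
  swarm_day <- sample(round(days * 0.5):round(days * 0.75), n_swarming,
                      replace = TRUE)
  swarm_hour <- stats::runif(n_swarming, 12, 15)
  toot_delay <- sample(4:7, n_swarming, replace = TRUE)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sw <- i <= n_swarming
    cid <- sprintf("%s-%02d", if (sw) "sw" else "ns", i)
    if (sw) {
      s_time <- as.POSIXct(paste(format(season_start + swarm_day[i]),
                                 "00:00:00"), tz = "UTC") +
        swarm_hour[i] * 3600
      a_times <- s_time + c(9, 13) * 86400
      season_end <- season_start + days
      a_times <- a_times[a_times <
                           as.POSIXct(paste(format(season_end),
                                            "00:00:00"), tz = "UTC")]
      out[[i]] <- hive_scenario(
        colony_id = cid, season_start = season_start,
        season_end = season_end, swarming = TRUE,
        primary_swarm_time = s_time, afterswarm_times = a_times,
        sig_gain = sig_gain,
        pipe_schedule = default_pipe_schedule(s_time, a_times,
                                              toot_delay[i]),
        rng_seed = (seed - 1) * 100 + i)
    } else {
      out[[i]] <- hive_scenario(
        colony_id = cid, season_start = season_start,
        season_end = season_start + days, swarming = FALSE,
        rng_seed = (seed - 1) * 100 + i)
    }
  }
  out
}

last_pipe_date <- function(scenario) {
  if (!is.null(scenario$pipe_schedule) && nrow(scenario$pipe_schedule))
    as.Date(format(max(scenario$pipe_schedule$end)))
  else if (scenario$swarming)
    as.Date(format(scenario$primary_swarm_time))
  else NA
}

#' Ground-truth night labels of a scenario
#'
#' Assigns each season night (the 00:00-05:00 window of a date) to the
#' preparing-to-swarm class (the \code{ramp_days} nights up to and
#' including the swarm morning), the non-swarming class (nights entirely
#' before the ramp, nights of non-swarming colonies, and nights after the
#' last queen pipe), or \code{NA} for the transitional span between swarm
#' and last pipe, which is excluded from error accounting.
#'
#' @param scenario a \code{hive_scenario}.
#' @return Data frame with columns \code{date}, \code{label}.
#' @export
night_labels <- function(scenario) {
  dates <- seq(scenario$season_start, scenario$season_end - 1, by = "day")
  if (!scenario$swarming)
    return(data.frame(date = dates, label = "NS"))
  S <- as.Date(format(scenario$primary_swarm_time))
  L <- last_pipe_date(scenario)
  label <- rep(NA_character_, length(dates))
  label[dates >= S - scenario$ramp_days + 1 & dates <= S] <- "PTS"
  label[dates <= S - scenario$ramp_days] <- "NS"
  label[dates > L] <- "NS"
  data.frame(date = dates, label = label)
}

#' Ground-truth labels for spectral-evolution windows
#'
#' Labels each possible \code{history_days}-day 3DFT end date: PTS when
#' the end date falls in the \code{pts_days} days up to the swarm (the
#' window then spans the signature ramp), NS when the whole history
#' precedes the ramp or follows the last queen pipe (or always, for
#' non-swarming colonies), \code{NA} for transitional windows.
#'
#' @param scenario a \code{hive_scenario}.
#' @param history_days 3DFT history length.
#' @param pts_days how many end dates before the swarm count as PTS
#'   (default 6, the span used to assemble the swarming training
#'   database).
#' @return Data frame with columns \code{date} (window end date),
#'   \code{label}.
#' @export
window_labels <- function(scenario, history_days = 10, pts_days = 6) {
  dates <- seq(scenario$season_start + history_days - 1,
               scenario$season_end - 1, by = "day")
  if (!scenario$swarming)
    return(data.frame(date = dates, label = "NS"))
  S <- as.Date(format(scenario$primary_swarm_time))
  L <- last_pipe_date(scenario)
  label <- rep(NA_character_, length(dates))
  label[dates >= S - pts_days + 1 & dates <= S] <- "PTS"
  label[dates <= S - scenario$ramp_days] <- "NS"
  label[dates - history_days + 1 > L] <- "NS"
  data.frame(date = dates, label = label)
}

# raw 03:00-04:00 (cfg$train_hour) mean spectrum per season date
night_raw_matrix <- function(series, cfg) {
  dates <- seq(as.Date(format(min(series$times))),
               as.Date(format(max(series$times))), by = "day")
  out <- matrix(NA_real_, length(dates), series$grid$n_bins)
  for (i in seq_along(dates)) {
    fr <- hourly_average(series, dates[i], cfg$train_hour[1],
                         cfg$train_hour[2])
    if (fr$quality == "ok") out[i, ] <- fr$amplitudes
  }
  rownames(out) <- format(dates)
  out
}

s1_featurise <- function(raw, grid, cfg) {
  idx <- crop_indices(grid, cfg$f_lo, cfg$f_hi)
  X <- raw[, idx, drop = FALSE]
  if (cfg$normalise == "divide") X <- X / rowMeans(X)
  else if (cfg$normalise == "subtract") X <- X - rowMeans(X)
  if (cfg$log_scale) X <- log10(X)
  X
}

# split a run of dates into pools of `len` consecutive days (>= min_len)
date_pools <- function(dates, len = 13, min_len = 7) {
  if (!length(dates)) return(list())
  runs <- split(dates, cumsum(c(TRUE, diff(dates) != 1)))
  pools <- list()
  for (r in runs) {
    nchunk <- max(1L, floor(length(r) / len))
    for (k in seq_len(nchunk)) {
      chunk <- r[((k - 1L) * len + 1L):min(k * len, length(r))]
      if (k == nchunk) chunk <- r[((k - 1L) * len + 1L):length(r)]
      if (length(chunk) >= min_len)
        pools[[length(pools) + 1L]] <- chunk
    }
  }
  pools
}

even_subset <- function(n, k) {
  if (n <= k) return(seq_len(n))
  unique(round(seq(1, n, length.out = k)))
}

valid_end_dates <- function(series, cfg) {
  dates <- seq(as.Date(format(min(series$times))),
               as.Date(format(max(series$times))), by = "day")
  usable <- vapply(dates, function(d)
    day_usable(series, d, cfg$window), logical(1))
  D <- cfg$history_days
  ok <- vapply(seq_along(dates), function(i)
    i >= D && all(usable[(i - D + 1L):i]), logical(1))
  list(dates = dates, usable = usable, valid = ok)
}

colony_s2_features <- function(series, cfg, end_dates = NULL) {
  cs <- crop_bandwidth(series, cfg$f_lo, cfg$f_hi)
  ve <- valid_end_dates(cs, cfg)
  images <- vector("list", length(ve$dates))
  for (i in which(ve$usable))
    images[[i]] <- daily_2dft(cs, ve$dates[i], cfg$window)
  D <- cfg$history_days
  sel <- which(ve$valid)
  if (!is.null(end_dates))
    sel <- sel[ve$dates[sel] %in% end_dates]
  feats <- lapply(sel, function(i)
    as.numeric(evolution_feature(evolution_3dft(images[(i - D + 1L):i]),
                                 cfg$normalise)))
  list(dates = ve$dates[sel],
       features = if (length(feats)) do.call(rbind, feats) else NULL)
}

update_alarm_threshold <- function(alarm, threshold) {
  alarm$threshold <- threshold
  alarm$hourly$triggered <- !alarm$hourly$missing &
    alarm$hourly$criterion < threshold
  alarm
}

#' Run the full synthetic swarm-prediction benchmark
#'
#' The package's reference experiment: simulate the standard cohort
#' ([cohort_scenarios()]), train both strategies on half the colonies
#' (first half of each class), and evaluate
#' \itemize{
#'   \item the held-out spectrum-level classification error of the
#'     instantaneous strategy (per-night 3-4 AM features, crop 18-800 Hz,
#'     mean-normalised, log, PCA keep fraction 0.4, 3 DFs, optimised
#'     threshold),
#'   \item the held-out window-level classification error of the
#'     spectral-evolution strategy (10-day 3DFTs, crop 25-800 Hz,
#'     midnight-5 AM windows),
#'   \item the colony-level success rate of each strategy over all
#'     colonies, from the nightly-mean alarm rules of
#'     [performance_summary()].
#' }
#' Training databases pool the ramp nights of each training swarming
#' colony into one PTS item and 13-night blocks of non-swarming nights
#' into NS items (capped at 24 PTS / 32 NS items); the evolution strategy
#' trains on up to 20 PTS and 21 NS windows.  Thresholds are re-optimised
#' over all labelled items of the training colonies, mirroring a training
#' phase in which held-out spectra still contribute to the clustering.
#'
#' @param seed master seed (drives the cohort layout and every colony
#'   simulation).
#' @param n_swarming,n_nonswarming,days cohort dimensions.
#' @param sig_gain planted signature gain.
#' @param verbose print progress.
#' @return An object of class \code{swarm_benchmark}: list with
#'   \code{spectrum_error}, \code{evolution_error},
#'   \code{success_instantaneous}, \code{success_evolution},
#'   \code{n_spectra}, \code{n_tensors}, the two fitted models, and the
#'   two \code{swarm_performance} summaries.
#' @export
swarm_benchmark <- function(seed = 1, n_swarming = 18, n_nonswarming = 14,
                            days = 60, sig_gain = 3.0, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  scenarios <- cohort_scenarios(n_swarming, n_nonswarming, days = days,
                                seed = seed, sig_gain = sig_gain)
  n <- length(scenarios)
  train_idx <- c(seq_len(ceiling(n_swarming / 2)),
                 n_swarming + seq_len(ceiling(n_nonswarming / 2)))
  cfg1 <- strategy_config("instantaneous")
  cfg2 <- strategy_config("evolution")

  # ---- training pass over the training-split colonies -----------------
  s1_pts <- list(); s1_ns <- list()
  s2_pts <- list(); s2_ns <- list()
  pts_quota <- max(1L, ceiling(20 / max(sum(train_idx <= n_swarming), 1)))
  ns_quota <- max(1L, ceiling(21 / length(train_idx)))
  for (i in train_idx) {
    sc <- scenarios[[i]]
    say("training pass: %s", sc$colony_id)
    sim <- simulate_series(sc)
    raw <- night_raw_matrix(sim$series, cfg1)
    nl <- night_labels(sc)
    pts_dates <- nl$date[!is.na(nl$label) & nl$label == "PTS"]
    ns_dates <- nl$date[!is.na(nl$label) & nl$label == "NS"]
    have <- as.Date(rownames(raw)[rowSums(is.na(raw)) == 0])
    if (sc$swarming && all(pts_dates %in% have))
      s1_pts[[length(s1_pts) + 1L]] <-
        colMeans(raw[format(pts_dates), , drop = FALSE])
    for (pool in date_pools(ns_dates[ns_dates %in% have]))
      s1_ns[[length(s1_ns) + 1L]] <-
        colMeans(raw[format(pool), , drop = FALSE])
    wl <- window_labels(sc, cfg2$history_days)
    if (sc$swarming) {
      pd <- wl$date[!is.na(wl$label) & wl$label == "PTS"]
      pd <- pd[even_subset(length(pd), pts_quota)]
      f <- colony_s2_features(sim$series, cfg2, pd)
      for (j in seq_len(NROW(f$features)))
        s2_pts[[length(s2_pts) + 1L]] <- f$features[j, ]
    }
    nd <- wl$date[!is.na(wl$label) & wl$label == "NS"]
    nd <- nd[even_subset(length(nd), ns_quota)]
    f <- colony_s2_features(sim$series, cfg2, nd)
    for (j in seq_len(NROW(f$features)))
      s2_ns[[length(s2_ns) + 1L]] <- f$features[j, ]
  }
  pool_db <- function(pts, ns, cap_pts, cap_ns) {
    pts <- pts[even_subset(length(pts), cap_pts)]
    ns <- ns[even_subset(length(ns), cap_ns)]
    list(x = do.call(rbind, c(pts, ns)),
         labels = c(rep("PTS", length(pts)), rep("NS", length(ns))))
  }
  db1_raw <- pool_db(s1_pts, s1_ns, 24, 32)
  grid <- scenarios[[1]]$grid
  db1 <- list(x = s1_featurise(db1_raw$x, grid, cfg1),
              labels = db1_raw$labels)
  db2 <- pool_db(s2_pts, s2_ns, 20, 21)
  say("fitting instantaneous model on %d items", nrow(db1$x))
  model1 <- swarm_dfa(db1$x, db1$labels, feature_cfg = cfg1)
  say("fitting evolution model on %d items", nrow(db2$x))
  model2 <- swarm_dfa(db2$x, db2$labels, feature_cfg = cfg2)

  # ---- scoring pass over every colony ---------------------------------
  alarms1 <- vector("list", n); alarms2 <- vector("list", n)
  events <- vector("list", n)
  crit1 <- list(); crit2 <- list()
  for (i in seq_len(n)) {
    sc <- scenarios[[i]]
    say("scoring pass: %s", sc$colony_id)
    sim <- simulate_series(sc)
    events[[i]] <- sim$events
    a1 <- hourly_alarm(sim$series, model1)
    a2 <- hourly_alarm(sim$series, model2)
    alarms1[[i]] <- a1; alarms2[[i]] <- a2
    nl <- night_labels(sc)
    h <- a1$hourly
    hh <- as.numeric(format(h$time, "%H"))
    night_crit <- h$criterion[hh == cfg1$train_hour[1]]
    night_date <- as.Date(format(h$time[hh == cfg1$train_hour[1]]))
    m <- match(nl$date, night_date)
    crit1[[i]] <- data.frame(colony = i, label = nl$label,
                             criterion = night_crit[m])
    wl <- window_labels(sc, cfg2$history_days)
    h2 <- a2$hourly
    midnight <- as.numeric(format(h2$time, "%H")) == 0
    dc <- h2$criterion[midnight]
    dd <- as.Date(format(h2$time[midnight]))
    m2 <- match(wl$date, dd)
    crit2[[i]] <- data.frame(colony = i, label = wl$label,
                             criterion = dc[m2])
  }
  c1 <- do.call(rbind, crit1); c2 <- do.call(rbind, crit2)
  usable1 <- !is.na(c1$label) & !is.na(c1$criterion)
  usable2 <- !is.na(c2$label) & !is.na(c2$criterion)
  tr1 <- usable1 & c1$colony %in% train_idx
  tr2 <- usable2 & c2$colony %in% train_idx
  thr1 <- optimize_threshold(c1$criterion[tr1], c1$label[tr1])
  thr2 <- optimize_threshold(c2$criterion[tr2], c2$label[tr2])
  model1$threshold <- thr1; model2$threshold <- thr2
  ho1 <- usable1 & !(c1$colony %in% train_idx)
  ho2 <- usable2 & !(c2$colony %in% train_idx)
  err1 <- 100 * mean((c1$criterion[ho1] < thr1) != (c1$label[ho1] == "PTS"))
  err2 <- 100 * mean((c2$criterion[ho2] < thr2) != (c2$label[ho2] == "PTS"))

  mk_cohort <- function(alarms, thr) {
    cl <- lapply(seq_len(n), function(i)
      list(alarm = update_alarm_threshold(alarms[[i]], thr),
           events = events[[i]], swarming = scenarios[[i]]$swarming))
    names(cl) <- vapply(scenarios, `[[`, "", "colony_id")
    cl
  }
  perf1 <- performance_summary(mk_cohort(alarms1, thr1))
  perf2 <- performance_summary(mk_cohort(alarms2, thr2))

  structure(list(
    spectrum_error = err1, evolution_error = err2,
    success_instantaneous = perf1$success_rate,
    success_evolution = perf2$success_rate,
    n_spectra = sum(ho1), n_tensors = sum(ho2), n_colonies = n,
    model_instantaneous = model1, model_evolution = model2,
    performance_instantaneous = perf1, performance_evolution = perf2,
    train_idx = train_idx, seed = seed),
    class = "swarm_benchmark")
}

#' @export
print.swarm_benchmark <- function(x, ...) {
  cat("Synthetic swarm-prediction benchmark\n")
  cat(sprintf("  cohort: %d colonies, training split %d\n",
              x$n_colonies, length(x$train_idx)))
  cat(sprintf("  instantaneous: %.2f%% held-out spectrum error (n=%d), %.1f%% colony success\n",
              x$spectrum_error, x$n_spectra, x$success_instantaneous))
  cat(sprintf("  evolution    : %.2f%% held-out 3DFT error (n=%d), %.1f%% colony success\n",
              x$evolution_error, x$n_tensors, x$success_evolution))
  cat(sprintf("  mean warning : %.1f days (instantaneous), %.1f days (evolution)\n",
              x$performance_instantaneous$mean_warning,
              x$performance_evolution$mean_warning))
  invisible(x)
}
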