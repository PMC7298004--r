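#' Hourly swarm-alarm time course
#'
#' Scores a colony's spectra stream with a trained model, one criterion
#' value per hour.  For the instantaneous strategy each hour's ok frames
#' are averaged, featurised (crop, mean-normalise, log) and scored; for the
#' spectral-evolution strategy the feature is the history-day 3DFT ending
#' on that day, and every hour of the day carries the day's value.  Hours
#' falling in data gaps are flagged missing, never scored as zero.
#'
#' @param series a \code{spectra_series} on the grid the model was trained
#'   for.
#' @param model a [swarm_dfa()] whose \code{feature_cfg} describes the
#'   strategy (see [strategy_config()]).
#' @return An object of class \code{alarm_series}: list with
#'   \code{hourly} (data frame: time, criterion, missing, triggered),
#'   \code{threshold}, \code{strategy}.
#' @export
hourly_alarm <- function(series, model) {
  stopifnot(inherits(series, "spectra_series"), inherits(model, "swarm_dfa"))
  cfg <- model$feature_cfg
  if (is.null(cfg)) cfg <- strategy_config("instantaneous")
  t0 <- as.POSIXct(format(min(series$times), "%Y-%m-%d"), tz = "UTC")
  t_end <- max(series$times)
  n_hours <- as.integer(ceiling((as.numeric(t_end) - as.numeric(t0)) /
                                  3600))
  hour_times <- t0 + (seq_len(n_hours) - 1) * 3600
  crit <- rep(NA_real_, n_hours)

  if (cfg$strategy == "instantaneous") {
    ok <- series$quality == "ok"
    hid <- floor((as.numeric(series$times) - as.numeric(t0)) / 3600) + 1L
    keep <- ok & hid >= 1L & hid <= n_hours
    if (any(keep)) {
      sums <- rowsum(series$amplitudes[keep, , drop = FALSE], hid[keep])
      counts <- as.vector(table(hid[keep]))
      hmeans <- sums / counts
      idx <- crop_indices(series$grid, cfg$f_lo, cfg$f_hi)
      X <- hmeans[, idx, drop = FALSE]
      if (cfg$normalise == "divide") X <- X / rowMeans(X)
      else if (cfg$normalise == "subtract") X <- X - rowMeans(X)
      if (cfg$log_scale) X <- log10(X)
      hrs <- as.integer(rownames(sums))
      crit[hrs] <- predict(model, X, type = "criterion")
    }
  } else {
    cs <- crop_bandwidth(series, cfg$f_lo, cfg$f_hi)
    days <- seq(as.Date(format(min(series$times))),
                as.Date(format(max(series$times))), by = "day")
    usable <- vapply(days, function(d)
      day_usable(cs, d, cfg$window), logical(1))
    images <- vector("list", length(days))
    for (i in which(usable))
      images[[i]] <- daily_2dft(cs, days[i], cfg$window)
    D <- cfg$history_days
    for (i in seq_along(days)) {
      if (i < D || !all(usable[(i - D + 1L):i])) next
      feat <- evolution_feature(
        evolution_3dft(images[(i - D + 1L):i]), cfg$normalise)
      value <- predict(model, as.numeric(feat), type = "criterion")
      day_start <- as.numeric(as.POSIXct(paste(format(days[i]),
                                               "00:00:00"), tz = "UTC"))
      hsel <- which(as.numeric(hour_times) >= day_start &
                      as.numeric(hour_times) < day_start + 86400)
      crit[hsel] <- value
    }
  }
  hourly <- data.frame(time = hour_times, criterion = crit,
                       missing = is.na(crit),
                       triggered = !is.na(crit) & crit < model$threshold)
  structure(list(hourly = hourly, threshold = model$threshold,
                 strategy = cfg$strategy),
            class = "alarm_series")
}

#' @export
print.alarm_series <- function(x, ...) {
  cat(sprintf(
    "<alarm_series> %s strategy: %d hours (%d missing, %d triggered), threshold %.3g\n",
    x$strategy, nrow(x$hourly), sum(x$hourly$missing),
    sum(x$hourly$triggered), x$threshold))
  invisible(x)
}

#' Strategy configuration for alarm scoring
#'
#' Bundles the preprocessing choices a trained model needs to score raw
#' spectra.  Defaults follow the optimised configurations: instantaneous
#' spectra are cropped 18-800 Hz, divided by their mean and
#' log10-transformed; spectral-evolution features crop 25-800 Hz, use the
#' midnight-5 AM window and a 10-day history, and are mean-normalised
#' without log.
#'
#' @param strategy \code{"instantaneous"} or \code{"evolution"}.
#' @param f_lo,f_hi crop band (Hz).
#' @param log_scale,normalise amplitude handling (instantaneous only uses
#'   \code{log_scale}).
#' @param window night analysis window, hours.
#' @param history_days 3DFT history length (evolution only).
#' @param train_hour training-night hour window for the instantaneous
#'   strategy (optimum 3-4 AM).
#' @param train_days days pooled into each swarming training item.
#' @return A list of class \code{strategy_config}.
#' @export
strategy_config <- function(strategy = c("instantaneous", "evolution"),
                            f_lo = NULL, f_hi = 800,
                            log_scale = NULL, normalise = "divide",
                            window = c(0, 5), history_days = 10,
                            train_hour = c(3, 4), train_days = 13) {
  strategy <- match.arg(strategy)
  if (is.null(f_lo)) f_lo <- if (strategy == "instantaneous") 18 else 25
  if (is.null(log_scale)) log_scale <- strategy == "instantaneous"
  structure(list(strategy = strategy, f_lo = f_lo, f_hi = f_hi,
                 log_scale = log_scale, normalise = normalise,
                 window = window, history_days = history_days,
                 train_hour = train_hour, train_days = train_days),
            class = "strategy_config")
}

#' Nightly mean alarm values
#'
#' Arithmetic mean of the non-missing hourly criterion values in the night
#' window of each day (default midnight to 5:00 AM).  A night with no
#' available hours is flagged missing, never reported as zero: power-cut
#' nights must not masquerade as strong alarms.
#'
#' @param alarm an \code{alarm_series}.
#' @param window numeric length 2, hours of day.
#' @return Data frame with columns \code{date}, \code{mean_criterion},
#'   \code{missing}, \code{triggered}.
#' @export
nightly_mean <- function(alarm, window = c(0, 5)) {
  stopifnot(inherits(alarm, "alarm_series"))
  h <- alarm$hourly
  hr <- as.numeric(format(h$time, "%H"))
  sel <- hr >= window[1] & hr < window[2]
  dates <- as.Date(format(h$time[sel]))
  vals <- h$criterion[sel]
  out <- do.call(rbind, lapply(split(seq_along(vals), dates), function(i) {
    v <- vals[i][!is.na(vals[i])]
    data.frame(mean_criterion = if (length(v)) mean(v) else NA_real_)
  }))
  out$date <- as.Date(rownames(out))
  out$missing <- is.na(out$mean_criterion)
  out$triggered <- !out$missing & out$mean_criterion < alarm$threshold
  rownames(out) <- NULL
  out[order(out$date), c("date", "mean_criterion", "missing", "triggered")]
}

sustained_runs <- function(nightly, min_nights = 2L) {
  trig <- nightly$triggered
  r <- rle(trig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 1L
  data.frame(start = nightly$date[starts[keep]],
             end = nightly$date[ends[keep]],
             nights = r$lengths[keep])
}

#' Swarm-warning lead time
#'
#' Days between the start of the earliest sustained run of triggered
#' nightly means and the swarm date.  A run is sustained when it spans at
#' least two consecutive triggered nights and persists to within two days
#' of the swarm; a trigger on the swarm date itself also counts (lead 0).
#' Returns \code{NA} when no such run exists.
#'
#' @param alarm an \code{alarm_series}.
#' @param swarm_time POSIXct primary swarm exit (within the alarm span).
#' @param window night window passed to [nightly_mean()].
#' @return Lead time in days, or \code{NA}.
#' @export
lead_time <- function(alarm, swarm_time, window = c(0, 5)) {
  nightly <- nightly_mean(alarm, window)
  swarm_date <- as.Date(format(swarm_time))
  runs <- sustained_runs(nightly)
  if (!nrow(runs)) return(NA_real_)
  valid <- (runs$nights >= 2L & runs$end >= swarm_date - 2 &
              runs$start <= swarm_date) |
    (runs$start <= swarm_date & runs$end >= swarm_date)
  if (!any(valid)) return(NA_real_)
  as.numeric(swarm_date - min(runs$start[valid]))
}

colony_truth <- function(events, swarming) {
  swarm_time <- NULL; last_pipe <- NULL
  if (nrow(events)) {
    ps <- events$time[events$kind == "primary_swarm"]
    if (length(ps)) swarm_time <- min(ps)
    cess <- events$time[events$kind %in% c("toot_cessation",
                                           "quack_cessation")]
    if (length(cess)) last_pipe <- max(cess)
  }
  if (swarming && is.null(swarm_time))
    stop("swarming colony lacks a primary_swarm event")
  list(swarm_time = swarm_time,
       not_intending_from = if (!swarming) -Inf
       else as.numeric(if (!is.null(last_pipe)) last_pipe else swarm_time))
}

#' Cohort performance summary
#'
#' Scores a cohort of colony alarms against ground truth, mirroring the
#' published performance accounting: nightly-mean alarm errors (swarming
#' colonies with no sustained pre-swarm trigger; non-swarming colonies with
#' a sustained trigger), raw hourly false positives (any hourly trigger
#' while the colony is not in a state of intending to swarm, i.e. a
#' non-swarming colony, or a swarming one after its last queen pipe), raw
#' hourly false negatives (no hourly trigger in the 14 days before the
#' primary swarm), mean predictive warning over correctly flagged swarming
#' colonies, and the colony-level success rate.
#'
#' @param colonies named list; each element is a list with components
#'   \code{alarm} (an \code{alarm_series}), \code{events} (an
#'   \code{event_log}) and \code{swarming} (logical truth label).
#' @param window night window for the nightly means.
#' @return An object of class \code{swarm_performance}: per-colony data
#'   frame plus aggregate counts and the success rate (percent).
#' @export
performance_summary <- function(colonies, window = c(0, 5)) {
  rows <- lapply(names(colonies), function(id) {
    col <- colonies[[id]]
    if (is.null(col$swarming) || is.na(col$swarming))
      stop("colony '", id, "' lacks a swarming truth label")
    truth <- colony_truth(col$events, col$swarming)
    h <- col$alarm$hourly
    nightly <- nightly_mean(col$alarm, window)
    runs <- sustained_runs(nightly)
    sustained <- runs[runs$nights >= 2L, , drop = FALSE]
    if (col$swarming) {
      lead <- lead_time(col$alarm, truth$swarm_time, window)
      nightly_ok <- !is.na(lead)
      raw_fn <- !any(h$triggered &
                       as.numeric(h$time) >=
                         as.numeric(truth$swarm_time) - 14 * 86400 &
                       as.numeric(h$time) <= as.numeric(truth$swarm_time))
      raw_fp <- any(h$triggered &
                      as.numeric(h$time) > truth$not_intending_from)
    } else {
      lead <- NA_real_
      nightly_ok <- nrow(sustained) == 0L
      raw_fn <- NA
      raw_fp <- any(h$triggered)
    }
    data.frame(colony = id, swarming = col$swarming, correct = nightly_ok,
               lead_days = lead, raw_false_positive = raw_fp,
               raw_false_negative = raw_fn)
  })
  tab <- do.call(rbind, rows)
  sw <- tab[tab$swarming, , drop = FALSE]
  ns <- tab[!tab$swarming, , drop = FALSE]
  out <- list(
    colonies = tab,
    n_swarming = nrow(sw), n_nonswarming = nrow(ns),
    mean_warning = if (any(sw$correct))
      mean(sw$lead_days[sw$correct]) else NA_real_,
    mean_alarm_errors_swarming = sum(!sw$correct),
    mean_alarm_errors_nonswarming = sum(!ns$correct),
    raw_fp_swarming = sum(sw$raw_false_positive),
    raw_fp_nonswarming = sum(ns$raw_false_positive),
    raw_fn_swarming = sum(sw$raw_false_negative),
    success_rate = 100 * mean(tab$correct))
  class(out) <- "swarm_performance"
  out
}

#' @export
print.swarm_performance <- function(x, ...) {
  cat("Cohort swarm-prediction performance\n")
  cat(sprintf("  colonies               : %d swarming, %d non-swarming\n",
              x$n_swarming, x$n_nonswarming))
  cat(sprintf("  mean predictive warning: %.1f days\n", x$mean_warning))
  cat(sprintf("  nightly-mean errors    : %d/%d swarming, %d/%d non-swarming\n",
              x$mean_alarm_errors_swarming, x$n_swarming,
              x$mean_alarm_errors_nonswarming, x$n_nonswarming))
  cat(sprintf("  raw hourly FP colonies : %d/%d swarming, %d/%d non-swarming\n",
              x$raw_fp_swarming, x$n_swarming,
              x$raw_fp_nonswarming, x$n_nonswarming))
  cat(sprintf("  raw hourly FN colonies : %d/%d swarming\n",
              x$raw_fn_swarming, x$n_swarming))
  cat(sprintf("  colony-level success   : %.1f%%\n", x$success_rate))
  invisible(x)
}
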