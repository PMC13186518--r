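#' Single-component cosinor fit
#'
#' Fits `y(t) = M + A * cos(2*pi*(t - t_peak)/period)` by exact linear least
#' squares: `y` is regressed on `cos(w t)` and `sin(w t)` with
#' `w = 2*pi/period`, then `A = sqrt(beta^2 + gamma^2)` and the acrophase
#' (clock time of peak) is `atan2(gamma, beta)/w` modulo the period. The
#' mesor `M` is the rhythm-adjusted mean. `r_squared = 1 - SSE/SST` measures
#' the fraction of variance the rhythm explains; a constant series has
#' amplitude 0 and, by convention, `r_squared = 0`.
#'
#' @param times Numeric times in hours.
#' @param counts Activity counts (finite) at those times.
#' @param period Rhythm period in hours (default 24).
#' @return A list of class `cosinor_fit`: `mesor`, `amplitude`,
#'   `acrophase_time` (hours in `[0, period)`), `r_squared`, `period`, `n`.
#' @export
#' @examples
#' t <- seq(0, 23.5, by = 0.5)
#' fit <- fit_cosinor(t, 50 + 30 * cos(2 * pi * (t - 15) / 24))
#' fit$acrophase_time  # 15
fit_cosinor <- function(times, counts, period = 24) {
  ok <- is.finite(times) & is.finite(counts)
  times <- times[ok]; counts <- counts[ok]
  if (length(unique(times)) < 3) {
    abort("cosinor fit needs >= 3 distinct time points.")
  }
  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  qrx <- qr(X)
  if (qrx$rank < 3) abort("degenerate cosinor design (times do not span the period).")
  beta <- qr.coef(qrx, counts)
  fitted <- drop(X %*% beta)
  sse <- sum((counts - fitted)^2)
  sst <- sum((counts - mean(counts))^2)
  amp <- sqrt(beta[2]^2 + beta[3]^2)
  acro <- if (amp == 0) 0 else (atan2(beta[3], beta[2]) / w) %% period
  structure(
    list(mesor = unname(beta[1]), amplitude = unname(amp),
         acrophase_time = unname(acro),
         r_squared = if (sst > 0) max(0, 1 - sse / sst) else 0,
         period = period, n = length(counts)),
    class = "cosinor_fit"
  )
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "cosinor fit (period %g h, n = %d)\n  mesor %.3f  amplitude %.3f  acrophase %.2f h  R^2 %.3f\n",
    x$period, x$n, x$mesor, x$amplitude, x$acrophase_time, x$r_squared))
  invisible(x)
}

#' Rhythm strength of one day
#'
#' Variance explained (R^2) by the day's 24-h single-component cosinor fit:
#' 1 for a noiseless sinusoid, near 0 for arrhythmic activity, and monotone
#' in between as noise grows.
#'
#' @inheritParams fit_cosinor
#' @return Proportion in `[0, 1]`.
#' @export
circadian_rhythm_strength <- function(times, counts, period = 24) {
  fit_cosinor(times, counts, period)$r_squared
}

# mean of x over each length-`width` sliding window, NA entries excluded;
# cumulative sums keep this O(n)
sliding_window_mean <- function(x, width) {
  n <- length(x)
  valid <- !is.na(x)
  xv <- ifelse(valid, x, 0)
  cs <- c(0, cumsum(xv))
  cn <- c(0, cumsum(valid))
  starts <- seq_len(n - width + 1L)
  sums <- cs[starts + width] - cs[starts]
  cnt <- cn[starts + width] - cn[starts]
  ifelse(cnt > 0, sums / cnt, NA_real_)
}

# hourly (or `bin_minutes`) means of one day's epochs, NA = off-wrist
bin_means <- function(counts, epoch_length, bin_minutes = 60) {
  per_bin <- as.integer(round(bin_minutes * 60 / epoch_length))
  bins <- (seq_along(counts) - 1L) %/% per_bin
  as.numeric(tapply(counts, bins, mean, na.rm = TRUE))
}

#' Nonparametric rest-activity features of one day
#'
#' Computes, from one full midnight-to-midnight day of epochs:
#' mean and SD of activity; RMSSD (root mean square of successive epoch
#' differences); intradaily variability (IV) on hourly means,
#' `IV = n * sum(diff(x)^2) / ((n - 1) * sum((x - mean(x))^2))`, which is
#' near 0 for a smooth 24-h sinusoid and near 2 for white noise; M10 and L5,
#' the largest/smallest mean activity over all consecutive 10-h/5-h windows
#' sliding at epoch resolution without wrapping midnight; and relative
#' amplitude `RA = (M10 - L5)/(M10 + L5)`. Off-wrist epochs are passed as
#' `NA` and excluded from every mean (a day that reaches this function has
#' already survived the off-wrist QC rule).
#'
#' @param counts Numeric vector covering exactly 24 h of epochs; `NA` marks
#'   off-wrist epochs.
#' @param epoch_length Epoch duration in seconds (default 30).
#' @param bin_minutes Bin width for the IV hourly means (default 60).
#' @return One-row tibble: `mean_activity`, `sd_activity`, `rmssd_activity`,
#'   `intradaily_variability`, `m10`, `l5`, `relative_amplitude`. IV is `NA`
#'   for a constant day; RA is `NA` when `m10 + l5 == 0`.
#' @export
nonparametric_day_features <- function(counts, epoch_length = 30,
                                       bin_minutes = 60) {
  per_day <- as.integer(round(86400 / epoch_length))
  if (length(counts) != per_day) {
    abort("nonparametric_day_features needs exactly one full 24-h day of epochs.")
  }
  obs <- counts[!is.na(counts)]
  mean_activity <- mean(obs)
  sd_activity <- sd(obs)
  d <- diff(obs)
  rmssd <- if (length(d)) sqrt(mean(d^2)) else NA_real_

  hourly <- bin_means(counts, epoch_length, bin_minutes)
  hourly <- hourly[is.finite(hourly)]
  nh <- length(hourly)
  denom <- sum((hourly - mean(hourly))^2)
  iv <- if (nh >= 2 && denom > 0) {
    nh * sum(diff(hourly)^2) / ((nh - 1) * denom)
  } else NA_real_

  m10 <- max(sliding_window_mean(counts, as.integer(round(10 * 3600 / epoch_length))),
             na.rm = TRUE)
  l5 <- min(sliding_window_mean(counts, as.integer(round(5 * 3600 / epoch_length))),
            na.rm = TRUE)
  ra <- if ((m10 + l5) > 0) (m10 - l5) / (m10 + l5) else NA_real_
  tibble::tibble(mean_activity = mean_activity, sd_activity = sd_activity,
                 rmssd_activity = rmssd, intradaily_variability = iv,
                 m10 = m10, l5 = l5, relative_amplitude = ra)
}

#' Interdaily stability across a participant's retained days
#'
#' `IS = (n * sum_h (xbar_h - xbar)^2) / (p * sum_i (x_i - xbar)^2)` over
#' the pooled hourly means of all retained days, where `xbar_h` is the mean
#' over days for hour-of-day `h`, `p = 24` hourly bins and `n` the total
#' number of hourly values. IS is 1 when the 24-h profile repeats exactly
#' across days and has expectation `1/n_days` for day-independent noise.
#' A recording-level quantity: the pipeline broadcasts it to each of the
#' participant's day rows.
#'
#' @param day_counts List of numeric vectors, one full 24-h day of epochs
#'   each (`NA` = off-wrist).
#' @param epoch_length Epoch duration in seconds.
#' @param bin_minutes Hourly bin width (default 60).
#' @return IS in `[0, 1]`, or `NA` with fewer than 2 days or a constant
#'   record.
#' @export
interdaily_stability <- function(day_counts, epoch_length = 30,
                                 bin_minutes = 60) {
  if (length(day_counts) < 2) return(NA_real_)
  hourly <- vapply(day_counts, bin_means, numeric(24 * 60 / bin_minutes),
                   epoch_length = epoch_length, bin_minutes = bin_minutes)
  x <- as.numeric(hourly)           # column-major: hours within day
  hour_of_day <- rep(seq_len(nrow(hourly)), times = ncol(hourly))
  ok <- is.finite(x)
  x <- x[ok]; hour_of_day <- hour_of_day[ok]
  n <- length(x)
  p <- length(unique(hour_of_day))
  xbar <- mean(x)
  hour_means <- tapply(x, hour_of_day, mean)
  denom <- p * sum((x - xbar)^2)
  if (denom == 0) return(NA_real_)
  min(1, n * sum((hour_means - xbar)^2) / denom)
}

#' Compute all objective features for the retained days of a cohort
#'
#' For each retained participant-day: a 24-h cosinor fit (mesor, amplitude,
#' acrophase time, and its R^2 as circadian rhythm strength) and the
#' nonparametric day features, with off-wrist epochs excluded from feature
#' sums; interdaily stability is computed once per participant over all of
#' their retained days and broadcast.
#'
#' @param epochs An [epoch_series()], list of them, or bound epoch tibble.
#' @param days Day table from [apply_exclusions()]; only `retained` rows are
#'   scored.
#' @param bin_minutes IV/IS bin width in minutes (default 60).
#' @return Tibble keyed by `participant_id`, `date`, `day_index` with the
#'   objective circadian feature columns.
#' @export
circadian_day_features <- function(epochs, days, bin_minutes = 60) {
  ep <- bind_epochs(epochs)
  len <- epoch_length(ep)
  keep <- days[days$retained, , drop = FALSE]
  if (nrow(keep) == 0) return(tibble::tibble())
  ep_date <- as.Date(ep$timestamp, tz = "UTC")
  hours_of_day <- (as.numeric(ep$timestamp) %% 86400) / 3600
  day_idx <- split(seq_len(nrow(ep)), paste(ep$participant_id, ep_date))

  day_counts <- lapply(seq_len(nrow(keep)), function(i) {
    sel <- day_idx[[paste(keep$participant_id[i], keep$date[i])]]
    list(counts = ifelse(ep$off_wrist[sel], NA_real_, ep$activity[sel]),
         times = hours_of_day[sel])
  })
  rows <- purrr::pmap_dfr(
    list(keep$participant_id, keep$date, keep$day_index, day_counts),
    function(participant_id, date, day_index, dc) {
      obs <- !is.na(dc$counts)
      fit <- fit_cosinor(dc$times[obs], dc$counts[obs])
      dplyr::bind_cols(
        tibble::tibble(participant_id = participant_id, date = date,
                       day_index = day_index,
                       mesor = fit$mesor, acrophase_time = fit$acrophase_time,
                       amplitude = fit$amplitude,
                       circadian_rhythm_strength = fit$r_squared),
        nonparametric_day_features(dc$counts, epoch_length = len,
                                   bin_minutes = bin_minutes)
      )
    }
  )
  is_by_person <- vapply(split(day_counts, keep$participant_id), function(lst) {
    interdaily_stability(lapply(lst, `[[`, "counts"), epoch_length = len,
                         bin_minutes = bin_minutes)
  }, numeric(1))
  rows$interdaily_stability <- unname(is_by_person[rows$participant_id])
  rows
}

#' Assemble the day-level feature table
#'
#' Joins the objective circadian features, the night sleep metrics and the
#' subjective log ratings into one row per retained participant-day, in the
#' stable column order of [feature_names()]. Rows missing any required
#' feature (e.g. a night with no qualifying sleep run) are dropped with a
#' message.
#'
#' @param circadian Output of [circadian_day_features()].
#' @param nights Output of [score_nights()].
#' @param sleep_logs Sleep-log tibble.
#' @return Day-feature tibble: `participant_id`, `day_index`, `date`, then
#'   the 18 feature columns.
#' @export
assemble_day_rows <- function(circadian, nights, sleep_logs) {
  if (is.null(circadian) || nrow(circadian) == 0) {
    return(tibble::tibble())
  }
  for (d in list(circadian, nights)) {
    if (anyDuplicated(d[c("participant_id", "date")])) {
      abort("duplicate (participant, date) keys in feature inputs.")
    }
  }
  logs <- sleep_logs |>
    dplyr::select("participant_id", date = "log_date", "quality", "restfulness")
  out <- circadian |>
    dplyr::left_join(dplyr::select(nights, "participant_id", "date",
                                   "total_sleep_time", "efficiency", "waso",
                                   "fragmentation"),
                     by = c("participant_id", "date")) |>
    dplyr::left_join(logs, by = c("participant_id", "date"))
  req <- feature_names()
  complete <- stats::complete.cases(out[req])
  if (any(!complete)) {
    message(sum(!complete), " day row(s) dropped for missing features.")
  }
  out[complete, c("participant_id", "day_index", "date", req)]
}
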