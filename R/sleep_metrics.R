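#' Default weighted scoring kernel
#'
#' Weights applied to the activity counts of the scored epoch and its
#' neighbours (+/- 2 min at 30-s epochs) before comparing the weighted sum
#' with the wake threshold. The centre weight dominates so a single large
#' count wakes its own epoch; the tapering side weights wake the surrounding
#' epochs only when the spike is large, mimicking published weighted-window
#' actigraphy scorers.
#' @return Numeric vector of odd length (the centre entry scores the epoch).
#' @export
default_scoring_kernel <- function() {
  c(0.04, 0.04, 0.2, 0.2, 2, 0.2, 0.2, 0.04, 0.04)
}

#' Score epochs within a rest interval as sleep or wake
#'
#' An epoch is scored sleep when the kernel-weighted moving sum of activity
#' counts centred on it is strictly below `threshold`; counts beyond the
#' interval edges are taken as zero. `threshold` follows the conventional
#' low/medium/high sensitivity settings (20/40/80); the default is the
#' medium setting, 40.
#'
#' @param counts Numeric vector of epoch activity counts inside the rest
#'   interval (bed time to rise time).
#' @param kernel Symmetric weight vector of odd length; see
#'   [default_scoring_kernel()].
#' @param threshold Wake threshold (> 0); default 40.
#' @return Logical vector, `TRUE` = sleep.
#' @export
#' @examples
#' score_epochs(rep(0, 10))          # all sleep
#' score_epochs(rep(1000, 10))       # all wake
score_epochs <- function(counts, kernel = default_scoring_kernel(),
                         threshold = 40) {
  if (length(kernel) %% 2 == 0) abort("scoring kernel length must be odd.")
  if (threshold <= 0) abort("wake threshold must be positive.")
  half <- (length(kernel) - 1L) / 2L
  padded <- c(rep(0, half), counts, rep(0, half))
  # stats::filter computes the centred weighted moving sum
  wsum <- stats::filter(padded, rev(kernel), method = "convolution", sides = 2)
  wsum <- as.numeric(wsum[(half + 1L):(half + length(counts))])
  wsum < threshold
}

# maximal runs of a logical vector: tibble with start, end, length, value
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  tibble::tibble(start = ends - r$lengths + 1L, end = ends,
                 length = r$lengths, value = r$values)
}

#' Night sleep metrics from a scored rest interval
#'
#' Sleep onset is the first run of at least `onset_run_minutes` consecutive
#' scored-sleep minutes and sleep offset the end of the last such run; total
#' sleep time (TST) and wake after sleep onset (WASO) are the sleep and wake
#' minutes between them. Efficiency is `100 * TST / interval duration`
#' (bed-to-rise denominator). The fragmentation index is the sum of the
#' movement index (percent of interval epochs with any activity) and the
#' immobility-fragmentation index (percent of immobile bouts lasting at most
#' one minute), matching the composite "sleep fragmentation index" reported
#' by clinical actigraphy software.
#'
#' @param counts Activity counts inside the rest interval.
#' @param sleep Logical sleep scores aligned to `counts` (see
#'   [score_epochs()]).
#' @param epoch_length Epoch duration in seconds (default 30).
#' @param onset_run_minutes Minimum run of scored sleep that qualifies as
#'   onset/offset (default 10).
#' @return One-row tibble: `total_sleep_time`, `waso` (minutes),
#'   `efficiency` (percent), `fragmentation`, `onset_epoch`, `offset_epoch`
#'   (1-based indices into the interval), or all-`NA` when no qualifying
#'   sleep run exists.
#' @export
night_metrics <- function(counts, sleep, epoch_length = 30,
                          onset_run_minutes = 10) {
  stopifnot(length(counts) == length(sleep))
  ep_min <- epoch_length / 60
  need <- ceiling(onset_run_minutes / ep_min)
  runs <- logical_runs(sleep)
  qual <- runs[runs$value & runs$length >= need, ]
  if (nrow(qual) == 0) {
    return(tibble::tibble(total_sleep_time = NA_real_, waso = NA_real_,
                          efficiency = NA_real_, fragmentation = NA_real_,
                          onset_epoch = NA_integer_, offset_epoch = NA_integer_))
  }
  onset <- qual$start[1]
  offset <- qual$end[nrow(qual)]
  span <- sleep[onset:offset]
  tst <- sum(span) * ep_min
  waso <- sum(!span) * ep_min
  duration <- length(counts) * ep_min

  movement_index <- 100 * mean(counts > 0)
  immobile_runs <- logical_runs(counts == 0)
  immobile_runs <- immobile_runs[immobile_runs$value, ]
  ifi <- if (nrow(immobile_runs) == 0) 0 else {
    100 * mean(immobile_runs$length * ep_min <= 1)
  }
  tibble::tibble(
    total_sleep_time = tst,
    waso = waso,
    efficiency = 100 * tst / duration,
    fragmentation = movement_index + ifi,
    onset_epoch = as.integer(onset),
    offset_epoch = as.integer(offset)
  )
}

#' Score every logged night of a cohort
#'
#' For each sleep-log row, slices the participant's epoch series to the
#' bed-to-rise rest interval, scores it, and computes night metrics keyed by
#' participant and waking date.
#'
#' @param epochs A single [epoch_series()] or a list of them (one per
#'   participant), or a row-bound tibble with the same columns.
#' @param sleep_logs Sleep-log tibble.
#' @param kernel,threshold,onset_run_minutes Passed to [score_epochs()] and
#'   [night_metrics()].
#' @return Tibble keyed by `participant_id`, `date` with the night-metric
#'   columns.
#' @export
score_nights <- function(epochs, sleep_logs,
                         kernel = default_scoring_kernel(), threshold = 40,
                         onset_run_minutes = 10) {
  ep <- bind_epochs(epochs)
  len <- epoch_length(ep)
  by_pid <- split(tibble::as_tibble(ep)[c("timestamp", "activity")],
                  ep$participant_id)
  purrr::pmap_dfr(
    sleep_logs[c("participant_id", "log_date", "bed_time", "rise_time")],
    function(participant_id, log_date, bed_time, rise_time) {
      pep <- by_pid[[participant_id]]
      counts <- if (is.null(pep)) numeric() else {
        pep$activity[pep$timestamp >= bed_time & pep$timestamp < rise_time]
      }
      if (length(counts) == 0) {
        return(tibble::tibble(participant_id = participant_id,
                              date = log_date, total_sleep_time = NA_real_,
                              waso = NA_real_, efficiency = NA_real_,
                              fragmentation = NA_real_,
                              onset_epoch = NA_integer_,
                              offset_epoch = NA_integer_))
      }
      sl <- score_epochs(counts, kernel, threshold)
      dplyr::bind_cols(
        tibble::tibble(participant_id = participant_id, date = log_date),
        night_metrics(counts, sl, epoch_length = len,
                      onset_run_minutes = onset_run_minutes)
      )
    }
  )
}

# accepts an epoch_series, a plain tibble of epoch rows, or a list of either
bind_epochs <- function(epochs) {
  if (inherits(epochs, "epoch_series") || is.data.frame(epochs)) return(epochs)
  len <- epoch_length(epochs[[1]])
  new_epoch_series(dplyr::bind_rows(lapply(epochs, tibble::as_tibble)), len)
}
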