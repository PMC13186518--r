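#' Segment an epoch series into midnight-to-midnight analysis days
#'
#' Each calendar date touched by the recording becomes one analysis day.
#' A day is `full_24h` only when it holds exactly 24 h of epochs (2880 at
#' 30 s); partial first/last days and wall-clock days shortened or stretched
#' by a clock change therefore fail the flag. `off_wrist_fraction` is the
#' proportion of the day's epochs flagged off-wrist.
#'
#' @param series An [epoch_series()].
#' @return A tibble with one row per calendar date: `participant_id`,
#'   `day_index` (1-based by date order), `date`, `n_epochs`,
#'   `off_wrist_fraction`, `full_24h`.
#' @export
segment_days <- function(series) {
  if (is.null(series) || nrow(series) == 0) abort("empty epoch series.")
  len <- epoch_length(series)
  per_day <- as.integer(round(86400 / len))
  series |>
    dplyr::mutate(date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::group_by(.data$participant_id, .data$date) |>
    dplyr::summarise(
      n_epochs = dplyr::n(),
      off_wrist_fraction = mean(.data$off_wrist),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$participant_id, .data$date) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(day_index = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(full_24h = .data$n_epochs == per_day) |>
    dplyr::select("participant_id", "day_index", "date", "n_epochs",
                  "off_wrist_fraction", "full_24h")
}

#' Apply day-level exclusion rules
#'
#' Marks each analysis day retained or excluded following the study-design
#' rules: days with >= `off_wrist_max` off-wrist time are dropped, as are
#' days without a completed morning sleep log, the clock-change day and the
#' `dst_exclusion_days` days after it, any day not covering a full 24 h, and
#' (unconditionally) the first and last study day, whose circadian measures
#' lack complete windows. With 7 clean days this leaves days 2-6: five
#' retained days per person.
#'
#' @param days Output of [segment_days()] (any number of participants
#'   row-bound together).
#' @param sleep_logs Sleep-log tibble ([read_sleep_logs()]); a day has a log
#'   when a row exists for that participant and waking date.
#' @param dst_events Optional tibble of clock changes with columns
#'   `participant_id` (optional; absent means "applies to everyone") and
#'   `date` of the transition.
#' @param off_wrist_max Exclusion threshold on the off-wrist proportion;
#'   days at or above it are dropped (default 0.30).
#' @param dst_exclusion_days Number of days after a transition to drop in
#'   addition to the transition day itself (default 2).
#' @param drop_first_last Drop each participant's first and last study day
#'   (default `TRUE`).
#' @return `days` with added logicals `has_sleep_log`, `dst_tainted`,
#'   `retained`, and `last_day_index`.
#' @export
apply_exclusions <- function(days, sleep_logs, dst_events = NULL,
                             off_wrist_max = 0.30, dst_exclusion_days = 2,
                             drop_first_last = TRUE) {
  log_keys <- if (!is.null(sleep_logs) && nrow(sleep_logs)) {
    paste(sleep_logs$participant_id, sleep_logs$log_date)
  } else character()
  out <- days |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(last_day_index = max(.data$day_index)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      has_sleep_log = paste(.data$participant_id, .data$date) %in% log_keys,
      dst_tainted = FALSE
    )
  if (!is.null(dst_events) && nrow(dst_events)) {
    for (i in seq_len(nrow(dst_events))) {
      ev <- dst_events[i, ]
      window <- seq(as.Date(ev$date), by = "day",
                    length.out = dst_exclusion_days + 1L)
      hit <- out$date %in% window
      if ("participant_id" %in% names(dst_events) && !is.na(ev$participant_id)) {
        hit <- hit & out$participant_id == ev$participant_id
      }
      out$dst_tainted <- out$dst_tainted | hit
    }
  }
  out |>
    dplyr::mutate(
      retained = .data$off_wrist_fraction < off_wrist_max &
        .data$has_sleep_log &
        !.data$dst_tainted &
        .data$full_24h &
        (!drop_first_last |
           (.data$day_index != 1L & .data$day_index != .data$last_day_index))
    )
}
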