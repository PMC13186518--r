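#' Construct an epoch series
#'
#' An epoch series is the raw material of every objective feature in the
#' package: one participant's wrist-actigraphy activity counts accumulated
#' over fixed-length epochs (30 s by default), with a parallel off-wrist
#' flag. The constructor enforces a gap-free, uniformly spaced grid; callers
#' with missing epochs should let [read_epoch_csv()] materialize them as
#' off-wrist zeros.
#'
#' @param participant_id Single string identifying the wearer.
#' @param start_time `POSIXct` local wall-clock time of the first epoch.
#'   Timestamps throughout the package are local wall-clock values carried in
#'   a fixed "UTC" tz; daylight-saving transitions are described separately
#'   via `timezone_events`, never via the OS timezone database.
#' @param counts Numeric vector of nonnegative, finite activity counts.
#' @param off_wrist Logical vector, same length as `counts`; `TRUE` marks
#'   epochs where the device was not worn.
#' @param epoch_length Epoch duration in seconds (default 30).
#' @param timezone_events Optional tibble with columns `time` (`POSIXct`) and
#'   `offset_change_min` recording clock changes (e.g. daylight saving)
#'   during the recording.
#'
#' @return A tibble of class `epoch_series` with columns `participant_id`,
#'   `timestamp`, `activity`, `off_wrist`, carrying `epoch_length` and
#'   `timezone_events` attributes.
#' @export
#' @examples
#' es <- epoch_series("p1", as.POSIXct("2024-03-04", tz = "UTC"),
#'                    counts = c(0, 10, 5), off_wrist = c(FALSE, FALSE, FALSE))
#' es
epoch_series <- function(participant_id, start_time, counts, off_wrist = NULL,
                         epoch_length = 30, timezone_events = NULL) {
  stopifnot(is.character(participant_id), length(participant_id) == 1)
  off_wrist <- off_wrist %||% rep(FALSE, length(counts))
  if (length(counts) < 1 || length(counts) != length(off_wrist)) {
    abort("`counts` and `off_wrist` must have equal length >= 1.")
  }
  if (anyNA(counts) || any(!is.finite(counts)) || any(counts < 0)) {
    abort("activity counts must be finite and nonnegative.")
  }
  start_time <- as.POSIXct(start_time, tz = "UTC")
  out <- tibble::tibble(
    participant_id = participant_id,
    timestamp = start_time + epoch_length * (seq_along(counts) - 1L),
    activity = as.numeric(counts),
    off_wrist = as.logical(off_wrist)
  )
  new_epoch_series(out, epoch_length, timezone_events)
}

# lenient ISO-8601 local wall-clock parser; unparseable entries become NA
parse_wallclock <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  miss <- is.na(out)
  if (any(miss)) {
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  }
  out
}

new_epoch_series <- function(df, epoch_length, timezone_events = NULL) {
  structure(
    df,
    epoch_length = epoch_length,
    timezone_events = timezone_events,
    class = c("epoch_series", class(tibble::tibble()))
  )
}

#' Epoch length of an epoch series
#' @param x An `epoch_series`.
#' @return Epoch duration in seconds.
#' @export
epoch_length <- function(x) attr(x, "epoch_length") %||% 30

#' Timezone-change events attached to an epoch series
#' @param x An `epoch_series`.
#' @return A tibble with columns `time`, `offset_change_min`, or `NULL`.
#' @export
timezone_events <- function(x) attr(x, "timezone_events")

#' Read an epoch-level actigraphy export
#'
#' Reads a CSV with columns `timestamp` (ISO-8601 local wall-clock),
#' `activity` (counts per epoch) and `off_wrist` (logical / 0-1), sorts
#' out-of-order rows, rejects duplicated timestamps, and materializes any
#' missing epochs as `off_wrist = TRUE`, `activity = 0` so the returned
#' series is gap-free and uniformly spaced. Gap filling never alters the sum
#' of observed counts.
#'
#' @param path Path to the CSV file.
#' @param epoch_length Epoch duration in seconds (default 30).
#' @param participant_id Identifier for the wearer; defaults to a
#'   `participant_id` column if present, else the file name without
#'   extension.
#' @param timezone_events Optional clock-change records (see
#'   [epoch_series()]).
#' @return An [epoch_series()] tibble.
#' @export
read_epoch_csv <- function(path, epoch_length = 30, participant_id = NULL,
                           timezone_events = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess(),
                                                 timestamp = readr::col_character()))
  need <- c("timestamp", "activity", "off_wrist")
  if (!all(need %in% names(raw))) {
    abort(paste0("epoch CSV must contain columns: ",
                 paste(need, collapse = ", ")))
  }
  ts <- parse_wallclock(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    abort(paste0("malformed timestamp in row ", bad, ": '",
                 raw$timestamp[bad], "'"))
  }
  if (anyNA(raw$activity) || any(raw$activity < 0)) {
    bad <- which(is.na(raw$activity) | raw$activity < 0)[1]
    abort(paste0("negative or missing activity count in row ", bad))
  }
  if (anyDuplicated(ts)) {
    abort("duplicated timestamps in epoch CSV.")
  }
  ord <- order(ts)
  ts <- ts[ord]
  activity <- as.numeric(raw$activity)[ord]
  off <- as.logical(raw$off_wrist)[ord]
  pid <- participant_id %||%
    (if ("participant_id" %in% names(raw)) as.character(raw$participant_id[1])
     else sub("\\.[^.]*$", "", basename(path)))

  grid <- seq(ts[1], ts[length(ts)], by = epoch_length)
  idx <- match(as.numeric(ts), as.numeric(grid))
  if (anyNA(idx)) {
    abort("epoch timestamps are not aligned to a uniform grid at `epoch_length`.")
  }
  activity_full <- numeric(length(grid))
  off_full <- rep(TRUE, length(grid))
  activity_full[idx] <- activity
  off_full[idx] <- off
  out <- tibble::tibble(participant_id = pid, timestamp = grid,
                        activity = activity_full, off_wrist = off_full)
  new_epoch_series(out, epoch_length, timezone_events)
}

#' Write an epoch series to CSV
#'
#' @param x An [epoch_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(x, path) {
  out <- tibble::tibble(
    participant_id = x$participant_id,
    timestamp = format(x$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    activity = x$activity,
    off_wrist = x$off_wrist
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read morning sleep logs
#'
#' One record per participant-morning: the previous night's in-bed and
#' out-of-bed times plus subjective sleep quality and restfulness, each rated
#' 1 (worst) to 10 (best) on waking. `log_date` is the calendar date of
#' waking, and the night's rest interval is assigned to that date throughout
#' the package.
#'
#' @param path CSV with columns `participant_id`, `log_date`, `bed_time`,
#'   `rise_time`, `quality`, `restfulness`.
#' @return A tibble, one row per participant-date, ratings as integers.
#' @export
read_sleep_logs <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_guess(),
                                                 bed_time = readr::col_character(),
                                                 rise_time = readr::col_character(),
                                                 log_date = readr::col_date()))
  need <- c("participant_id", "log_date", "bed_time", "rise_time",
            "quality", "restfulness")
  if (!all(need %in% names(raw))) {
    abort(paste0("sleep-log CSV must contain columns: ",
                 paste(need, collapse = ", ")))
  }
  out <- tibble::tibble(
    participant_id = as.character(raw$participant_id),
    log_date = as.Date(raw$log_date),
    bed_time = parse_wallclock(raw$bed_time),
    rise_time = parse_wallclock(raw$rise_time),
    quality = as.integer(round(raw$quality)),
    restfulness = as.integer(round(raw$restfulness))
  )
  validate_sleep_logs(out)
}

validate_sleep_logs <- function(out) {
  if (anyNA(out$bed_time) || anyNA(out$rise_time)) {
    abort("malformed bed_time/rise_time in sleep log.")
  }
  bad <- which(out$quality < 1L | out$quality > 10L |
                 out$restfulness < 1L | out$restfulness > 10L |
                 is.na(out$quality) | is.na(out$restfulness))
  if (length(bad)) {
    abort(paste0("sleep-log rating outside 1-10 in row ", bad[1]))
  }
  if (any(out$bed_time >= out$rise_time)) {
    abort("bed_time must precede rise_time in every sleep-log row.")
  }
  if (any(as.Date(out$rise_time, tz = "UTC") != out$log_date)) {
    abort("rise_time must fall on log_date for every sleep-log row.")
  }
  if (anyDuplicated(out[c("participant_id", "log_date")])) {
    abort("duplicate participant-date rows in sleep log.")
  }
  out
}

#' Write sleep logs to CSV
#' @param logs Tibble as returned by [read_sleep_logs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sleep_logs <- function(logs, path) {
  out <- dplyr::mutate(
    logs,
    bed_time = format(.data$bed_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    rise_time = format(.data$rise_time, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read the participant outcome table
#'
#' Clinician PTSD diagnosis (0/1, possibly missing for participants without
#' a structured interview), PCL-5 total symptom score (0-80), any current
#' non-PTSD diagnosis (0/1) and age in years. Probable-diagnosis flags at the
#' validated PCL-5 cutoffs of 31 and 38 are derived on read; by construction
#' `pcl38 == 1` implies `pcl31 == 1`.
#'
#' @param path CSV with columns `participant_id`, `ptsd_dx`, `pcl5_total`,
#'   `nonptsd_dx`, `age`.
#' @return A tibble with derived columns `pcl31`, `pcl38`.
#' @export
read_outcomes <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("participant_id", "ptsd_dx", "pcl5_total", "nonptsd_dx", "age")
  if (!all(need %in% names(raw))) {
    abort(paste0("outcomes CSV must contain columns: ",
                 paste(need, collapse = ", ")))
  }
  if (any(raw$pcl5_total < 0 | raw$pcl5_total > 80, na.rm = TRUE)) {
    abort("pcl5_total must lie in 0-80.")
  }
  if (anyDuplicated(raw$participant_id)) abort("duplicate participant_id in outcomes.")
  tibble::tibble(
    participant_id = as.character(raw$participant_id),
    ptsd_dx = as.integer(raw$ptsd_dx),
    pcl5_total = as.integer(raw$pcl5_total),
    pcl31 = as.integer(raw$pcl5_total >= 31),
    pcl38 = as.integer(raw$pcl5_total >= 38),
    nonptsd_dx = as.integer(raw$nonptsd_dx),
    age = as.numeric(raw$age)
  )
}

#' Write the participant outcome table to CSV
#' @param outcomes Tibble with at least the raw outcome columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_outcomes <- function(outcomes, path) {
  keep <- intersect(c("participant_id", "ptsd_dx", "pcl5_total",
                      "nonptsd_dx", "age"), names(outcomes))
  readr::write_csv(outcomes[keep], path, progress = FALSE)
  invisible(path)
}

# stable on-disk column order for the day-feature table; the CSV header
# documents it.
day_feature_columns <- function() {
  c("participant_id", "day_index", "date", feature_names(),
    "retained")
}

#' Names of the daily features
#'
#' The 18 features carried by each retained participant-day: 16 objective
#' (cosinor, nonparametric rest-activity and night-sleep metrics) plus the
#' two subjective morning ratings.
#' @return Character vector of feature column names.
#' @export
feature_names <- function() {
  c("mesor", "acrophase_time", "amplitude", "relative_amplitude",
    "mean_activity", "sd_activity", "rmssd_activity",
    "intradaily_variability", "interdaily_stability",
    "circadian_rhythm_strength", "m10", "l5",
    "total_sleep_time", "efficiency", "waso", "fragmentation",
    "quality", "restfulness")
}

#' Write and read the day-feature table
#'
#' A flat CSV with one row per retained participant-day in the stable column
#' order given by the header; `read_day_features(write_day_features(x))`
#' reproduces `x`.
#'
#' @param rows Nonempty day-feature tibble (see [assemble_day_rows()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_day_features <- function(rows, path) {
  if (nrow(rows) == 0) abort("no day-feature rows to write.")
  cols <- intersect(day_feature_columns(), names(rows))
  readr::write_csv(rows[cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_day_features
#' @export
read_day_features <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(participant_id = readr::col_character(),
                                          date = readr::col_date(),
                                          day_index = readr::col_integer(),
                                          .default = readr::col_double()))
}
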