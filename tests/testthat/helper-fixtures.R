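# shared fixtures, built in code; the default cohort is cached per session
# because several suites exercise it

fixture_cache <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

# one participant's sinusoidal epoch series starting at local midnight
make_sine_series <- function(days = 7, mesor = 50, amplitude = 30,
                             t_peak = 15, noise_sd = 0, epoch_length = 30,
                             id = "p1", start = "2024-03-04") {
  n <- days * 86400 / epoch_length
  t_h <- (seq_len(n) - 1) * epoch_length / 3600
  counts <- mesor + amplitude * cos(2 * pi * ((t_h %% 24) - t_peak) / 24)
  if (noise_sd > 0) counts <- counts + rnorm(n, 0, noise_sd)
  epoch_series(id, as.POSIXct(start, tz = "UTC"), pmax(0, counts),
               epoch_length = epoch_length)
}

# sleep logs covering waking dates 2..days for one participant
make_clean_logs <- function(days = 7, id = "p1", start = "2024-03-04",
                            quality = 7, restfulness = 7) {
  d0 <- as.Date(start)
  tibble::tibble(
    participant_id = id,
    log_date = d0 + seq(1, days - 1),
    bed_time = as.POSIXct(paste(d0 + seq(0, days - 2), "23:00:00"), tz = "UTC"),
    rise_time = as.POSIXct(paste(d0 + seq(1, days - 1), "07:00:00"), tz = "UTC"),
    quality = quality, restfulness = restfulness
  )
}

default_cohort <- function(seed = 20260901) {
  key <- paste0("cohort_", seed)
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- generate_cohort(cohort_config(seed = seed))
  }
  fixture_cache[[key]]
}

default_cohort_features <- function(seed = 20260901) {
  key <- paste0("features_", seed)
  if (is.null(fixture_cache[[key]])) {
    co <- default_cohort(seed)
    fixture_cache[[key]] <- derive_day_features(co$epochs, co$sleep_logs)
  }
  fixture_cache[[key]]
}

# small day-row table with a planted separable feature, for model tests
make_toy_rows <- function(n_person = 10, n_days = 3, effect = 3, seed = 1,
                          n_pos = NULL) {
  withr::with_seed(seed, {
    pid <- sprintf("s%02d", seq_len(n_person))
    labels <- setNames(rep(0L, n_person), pid)
    labels[seq_len(n_pos %||% (n_person / 2))] <- 1L
    rows <- tidyr::expand_grid(participant_id = pid, day = seq_len(n_days))
    rows$signal <- effect * labels[rows$participant_id] + rnorm(nrow(rows))
    rows$noise1 <- rnorm(nrow(rows))
    rows$noise2 <- rnorm(nrow(rows))
    list(rows = rows, labels = labels)
  })
}
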