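#' Synthetic cohort configuration
#'
#' Defines the generative study conditions for a fully synthetic actigraphy
#' cohort: a week of 30-s epochs for ~33 male veterans, a minority carrying
#' a PTSD diagnosis, with circadian activity structure, nightly rest
#' intervals, correlated subjective morning ratings, and signed group
#' differences in restfulness, WASO, sleep efficiency, fragmentation and
#' acrophase. Defaults mirror the emulated study design (n = 33 analysed
#' participants, 7 days, diagnosis prevalence 8/33, age 41 +/- 5.3 y,
#' quality-restfulness correlation 0.9) and effect signs follow the
#' person-level feature-outcome correlations that design reports (diagnosed
#' participants: lower restfulness, later acrophase, more WASO, lower
#' efficiency, more fragmented sleep).
#'
#' @param n_participants Number of participants (>= 4; default 33).
#' @param n_days Recording length in days (default 7).
#' @param epoch_length Epoch duration in seconds (default 30).
#' @param prevalence_dx Diagnosis prevalence (default 8/33); the diagnosed
#'   count is `round(prevalence_dx * n_participants)`.
#' @param delta_restfulness Diagnosed-group shift of the mean restfulness
#'   rating (default -1.5 points on the 1-10 scale).
#' @param delta_waso_minutes Diagnosed-group shift of planted nightly wake
#'   after sleep onset (default +20 min over a 30-min control base).
#' @param delta_efficiency Diagnosed-group shift of expected sleep
#'   efficiency in percentage points, realized as extra sleep-onset latency
#'   (default -4).
#' @param delta_fragmentation Diagnosed-group shift of the within-sleep
#'   movement blip probability, in percentage points of interval epochs
#'   (default +6; raises the fragmentation index).
#' @param delta_acrophase_hours Diagnosed-group shift of the activity peak
#'   time (default +1 h, i.e. a later acrophase).
#' @param rho_quality_restfulness Person-level correlation between the two
#'   subjective ratings (default 0.9).
#' @param age_mean,age_sd Age distribution in years (default 41, 5.3).
#' @param mesor,amplitude,t_peak Cosinor parameters of the control daytime
#'   activity signal (counts, counts, hours; defaults 200, 180, 15).
#' @param ar_phi AR(1) coefficient of the epoch-level activity noise
#'   (default 0.6, which yields intradaily variability between the smooth
#'   sinusoid and white-noise extremes).
#' @param noise_sd Stationary SD of the activity noise (default 60 counts).
#' @param bed_hour,rise_hour Mean bed and rise clock times (default 23, 7).
#' @param base_waso_minutes Control-group planted nightly WASO (default 30).
#' @param base_latency_minutes Control-group sleep-onset latency
#'   (default 10).
#' @param blip_prob Control-group probability that a within-sleep epoch
#'   carries a small movement blip (default 0.05).
#' @param rating_mean,rating_sd Person-level mean and SD of the subjective
#'   ratings (default 7.5, 1.2).
#' @param pcl_mean_ctrl,pcl_mean_dx,pcl_sd PCL-5 total generation (defaults
#'   20, 45, 8), calibrated so the >= 31 and >= 38 flags land near the
#'   emulated prevalences (~11/33 and ~7/33).
#' @param prevalence_nonptsd Probability of a non-PTSD current diagnosis,
#'   drawn independently of every feature (default 0.4) so discriminant
#'   validity holds by construction.
#' @param confound_nonptsd If `TRUE`, non-PTSD diagnosis also shifts
#'   restfulness and WASO (half the diagnosed effect), for probing the
#'   validity regressions under confounding.
#' @param seed Integer seed (required).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 33, n_days = 7, epoch_length = 30,
                          prevalence_dx = 8 / 33,
                          delta_restfulness = -1.5,
                          delta_waso_minutes = 20,
                          delta_efficiency = -4,
                          delta_fragmentation = 6,
                          delta_acrophase_hours = 1,
                          rho_quality_restfulness = 0.9,
                          age_mean = 41, age_sd = 5.3,
                          mesor = 200, amplitude = 180, t_peak = 15,
                          ar_phi = 0.6, noise_sd = 60,
                          bed_hour = 23, rise_hour = 7,
                          base_waso_minutes = 30, base_latency_minutes = 10,
                          blip_prob = 0.05,
                          rating_mean = 7.5, rating_sd = 1.2,
                          pcl_mean_ctrl = 20, pcl_mean_dx = 45, pcl_sd = 8,
                          prevalence_nonptsd = 0.4,
                          confound_nonptsd = FALSE,
                          seed = NULL) {
  if (is.null(seed)) abort("cohort_config requires a seed.")
  if (n_participants < 4) abort("n_participants must be >= 4.")
  if (prevalence_dx <= 0 || prevalence_dx >= 1 ||
      prevalence_nonptsd <= 0 || prevalence_nonptsd >= 1) {
    abort("prevalences must lie strictly between 0 and 1.")
  }
  cfg <- as.list(environment())
  class(cfg) <- "cohort_config"
  tr <- planted_truth(cfg)   # validates feasibility
  eff <- tr$diagnosed[tr$feature == "efficiency"]
  if (!is.na(eff) && eff <= 0) abort("infeasible effect configuration: diagnosed efficiency <= 0.")
  rest <- tr$diagnosed[tr$feature == "restfulness"]
  if (!is.na(rest) && (rest < 1 || rest > 10)) {
    abort("infeasible effect configuration: diagnosed restfulness outside 1-10.")
  }
  cfg
}

#' Planted generative truth of a cohort configuration
#'
#' The exact per-group parameter values the generator uses, so downstream
#' tests can assert recovery. Features whose values arise from the
#' interaction of signal, noise and clipping rather than from a directly
#' planted parameter are marked `emergent`, with the sign of the planted
#' group difference (if any) in `direction`.
#'
#' @param config A [cohort_config()].
#' @return Tibble: `feature`, `control`, `diagnosed`, `emergent`,
#'   `direction` (+1 / -1 / 0 expected sign of diagnosed minus control).
#' @export
planted_truth <- function(config) {
  interval_min <- ((24 - config$bed_hour) + config$rise_hour) * 60
  eff_ctrl <- 100 * (interval_min - config$base_latency_minutes -
                       config$base_waso_minutes) / interval_min
  lat_dx <- config$base_latency_minutes -
    config$delta_efficiency / 100 * interval_min
  eff_dx <- 100 * (interval_min - lat_dx - config$base_waso_minutes -
                     config$delta_waso_minutes) / interval_min
  tibble::tribble(
    ~feature, ~control, ~diagnosed, ~emergent, ~direction,
    "mesor", NA_real_, NA_real_, TRUE, 0,
    "acrophase_time", config$t_peak,
      config$t_peak + config$delta_acrophase_hours, FALSE,
      sign(config$delta_acrophase_hours),
    "amplitude", NA_real_, NA_real_, TRUE, 0,
    "relative_amplitude", NA_real_, NA_real_, TRUE, 0,
    "mean_activity", NA_real_, NA_real_, TRUE, 0,
    "sd_activity", NA_real_, NA_real_, TRUE, 0,
    "rmssd_activity", NA_real_, NA_real_, TRUE, 0,
    "intradaily_variability", NA_real_, NA_real_, TRUE, 0,
    "interdaily_stability", NA_real_, NA_real_, TRUE, 0,
    "circadian_rhythm_strength", NA_real_, NA_real_, TRUE, 0,
    "m10", NA_real_, NA_real_, TRUE, 0,
    "l5", NA_real_, NA_real_, TRUE, 0,
    "total_sleep_time",
      interval_min - config$base_latency_minutes - config$base_waso_minutes,
      interval_min - lat_dx - config$base_waso_minutes -
        config$delta_waso_minutes,
      FALSE, -1,
    "efficiency", eff_ctrl, eff_dx, FALSE, sign(eff_dx - eff_ctrl),
    "waso", config$base_waso_minutes,
      config$base_waso_minutes + config$delta_waso_minutes, FALSE,
      sign(config$delta_waso_minutes),
    "fragmentation", NA_real_, NA_real_, TRUE,
      sign(config$delta_fragmentation),
    "quality", config$rating_mean,
      config$rating_mean + 0.9 * config$delta_restfulness, FALSE,
      sign(config$delta_restfulness),
    "restfulness", config$rating_mean,
      config$rating_mean + config$delta_restfulness, FALSE,
      sign(config$delta_restfulness)
  )
}

# stationary AR(1) noise with marginal SD `sd`
ar1_noise <- function(n, phi, sd) {
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

#' Generate a complete synthetic study cohort
#'
#' Builds, deterministically for the configured seed, every input the
#' analysis pipeline consumes: per-participant epoch series (daytime
#' activity as an individual cosinor plus AR(1) noise clipped at zero;
#' nighttime suppression inside the rest interval with planted sleep
#' latency, brief high-activity wake bouts totalling the planted WASO, and
#' sparse low-amplitude movement blips), morning sleep logs whose two
#' subjective ratings are drawn jointly at the configured correlation, and
#' the participant outcome table (diagnosis, PCL-5 total, independent
#' non-PTSD diagnosis, age). Diagnosed participants receive the configured
#' signed shifts.
#'
#' @param config A [cohort_config()].
#' @param dir Optional directory; when given, writes `epochs_<id>.csv` per
#'   participant plus `sleep_logs.csv` and `outcomes.csv`, all readable by
#'   the package's readers without modification.
#' @return A list: `epochs` (named list of [epoch_series()]), `sleep_logs`,
#'   `outcomes`, `truth` ([planted_truth()]), `config`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, generate_cohort_impl(config, dir))
}

generate_cohort_impl <- function(cfg, dir) {
  n <- cfg$n_participants
  ids <- sprintf("p%02d", seq_len(n))
  n_dx <- round(cfg$prevalence_dx * n)
  dx <- as.integer(seq_len(n) %in% sample.int(n, n_dx))
  nonptsd <- rbinom(n, 1, cfg$prevalence_nonptsd)
  age <- round(rnorm(n, cfg$age_mean, cfg$age_sd), 1)
  pcl <- pmin(80L, pmax(0L, as.integer(round(
    rnorm(n, ifelse(dx == 1, cfg$pcl_mean_dx, cfg$pcl_mean_ctrl), cfg$pcl_sd)))))

  # person-level latent subjective ratings, bivariate normal at rho
  rho <- cfg$rho_quality_restfulness
  z1 <- rnorm(n); z2 <- rnorm(n)
  lat_rest <- z1
  lat_qual <- rho * z1 + sqrt(1 - rho^2) * z2
  rest_mean_i <- cfg$rating_mean + cfg$rating_sd * lat_rest +
    dx * cfg$delta_restfulness +
    (if (cfg$confound_nonptsd) nonptsd * cfg$delta_restfulness / 2 else 0)
  qual_mean_i <- cfg$rating_mean + cfg$rating_sd * lat_qual +
    dx * 0.9 * cfg$delta_restfulness

  per_day <- as.integer(round(86400 / cfg$epoch_length))
  start <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  interval_min <- ((24 - cfg$bed_hour) + cfg$rise_hour) * 60

  epochs <- vector("list", n)
  logs <- vector("list", n)
  for (i in seq_len(n)) {
    n_ep <- per_day * cfg$n_days
    tt <- (as.numeric(start + cfg$epoch_length * (seq_len(n_ep) - 1L)) %%
             86400) / 3600
    # person-level heterogeneity: real cohorts vary between subjects far
    # more than between nights within a subject
    tp_i <- cfg$t_peak + dx[i] * cfg$delta_acrophase_hours + rnorm(1, 0, 0.4)
    mesor_i <- rnorm(1, cfg$mesor, 25)
    amp_i <- rnorm(1, cfg$amplitude, 30)
    activity <- mesor_i + amp_i * cos(2 * pi * (tt - tp_i) / 24) +
      ar1_noise(n_ep, cfg$ar_phi, cfg$noise_sd)

    waso_i <- max(5, cfg$base_waso_minutes + dx[i] * cfg$delta_waso_minutes +
      (if (cfg$confound_nonptsd) nonptsd[i] * cfg$delta_waso_minutes / 2 else 0) +
      rnorm(1, 0, 8))
    lat_i <- max(2, cfg$base_latency_minutes -
      dx[i] * cfg$delta_efficiency / 100 * interval_min + rnorm(1, 0, 5))
    blip_i <- min(0.5, max(0.005,
      cfg$blip_prob + dx[i] * cfg$delta_fragmentation / 100 +
        rnorm(1, 0, 0.025)))
    bed_off_i <- rnorm(1, 0, 0.4)
    rise_off_i <- rnorm(1, 0, 0.4)

    night_rows <- vector("list", cfg$n_days - 1)
    for (d in seq_len(cfg$n_days - 1)) {
      bed <- start + (d - 1) * 86400 +
        (cfg$bed_hour + bed_off_i + rnorm(1, 0, 0.25)) * 3600
      rise <- start + d * 86400 +
        (cfg$rise_hour + rise_off_i + rnorm(1, 0, 0.25)) * 3600
      bed_ep <- as.integer(floor(as.numeric(bed - start, units = "secs") /
                                   cfg$epoch_length)) + 1L
      rise_ep <- as.integer(floor(as.numeric(rise - start, units = "secs") /
                                    cfg$epoch_length))
      n_int <- rise_ep - bed_ep + 1L
      ep_min <- cfg$epoch_length / 60
      night <- numeric(n_int)
      blips <- runif(n_int) < blip_i
      night[blips] <- rexp(sum(blips), rate = 1 / 12)
      lat_ep <- round(max(2, lat_i + rnorm(1, 0, 3)) / ep_min)
      night[seq_len(min(lat_ep, n_int))] <- 150 + rexp(min(lat_ep, n_int), 1 / 100)
      # planted wake bouts totalling ~waso_i minutes, well inside the night
      waso_night <- max(2, waso_i + rnorm(1, 0, 5))
      n_bouts <- max(1L, round(waso_night / 8))
      bout_len <- round(waso_night / n_bouts / ep_min)
      lo <- lat_ep + round(40 / ep_min)
      hi <- n_int - round(40 / ep_min) - bout_len
      if (hi > lo) {
        starts <- sort(sample(lo:hi, n_bouts))
        for (s in starts) {
          span <- s:min(s + bout_len - 1L, n_int)
          night[span] <- 150 + rexp(length(span), 1 / 100)
        }
      }
      activity[bed_ep:rise_ep] <- night

      q <- as.integer(pmin(10, pmax(1, round(qual_mean_i[i] + rnorm(1, 0, 0.4)))))
      r <- as.integer(pmin(10, pmax(1, round(rest_mean_i[i] + rnorm(1, 0, 0.4)))))
      night_rows[[d]] <- tibble::tibble(
        participant_id = ids[i],
        log_date = as.Date(start, tz = "UTC") + d,
        bed_time = bed - as.numeric(bed) %% cfg$epoch_length,
        rise_time = rise - as.numeric(rise) %% cfg$epoch_length,
        quality = q, restfulness = r)
    }
    activity <- pmax(0, activity)
    epochs[[i]] <- epoch_series(ids[i], start, activity,
                                epoch_length = cfg$epoch_length)
    logs[[i]] <- dplyr::bind_rows(night_rows)
  }
  names(epochs) <- ids
  sleep_logs <- dplyr::bind_rows(logs)
  outcomes <- tibble::tibble(
    participant_id = ids, ptsd_dx = dx, pcl5_total = pcl,
    pcl31 = as.integer(pcl >= 31), pcl38 = as.integer(pcl >= 38),
    nonptsd_dx = nonptsd, age = age)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in ids) {
      write_epoch_csv(epochs[[id]], file.path(dir, paste0("epochs_", id, ".csv")))
    }
    write_sleep_logs(sleep_logs, file.path(dir, "sleep_logs.csv"))
    write_outcomes(outcomes, file.path(dir, "outcomes.csv"))
  }
  list(epochs = epochs, sleep_logs = sleep_logs, outcomes = outcomes,
       truth = planted_truth(cfg), config = cfg)
}
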