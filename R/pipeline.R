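#' Derive the day-level feature table from raw cohort inputs
#'
#' Runs segmentation, day-level quality control, night sleep scoring and
#' circadian feature extraction, and assembles one row per retained
#' participant-day.
#'
#' @param epochs Named list of [epoch_series()] (or a single series).
#' @param sleep_logs Sleep-log tibble.
#' @param dst_events Optional clock-change table (see [apply_exclusions()]).
#' @param off_wrist_max,dst_exclusion_days,drop_first_last QC settings.
#' @param threshold,onset_run_minutes Sleep-scoring settings.
#' @param bin_minutes IV/IS bin width in minutes.
#' @return The day-feature tibble, with the QC day table attached as
#'   attribute `"qc_days"`.
#' @export
derive_day_features <- function(epochs, sleep_logs, dst_events = NULL,
                                off_wrist_max = 0.30, dst_exclusion_days = 2,
                                drop_first_last = TRUE, threshold = 40,
                                onset_run_minutes = 10, bin_minutes = 60) {
  if (inherits(epochs, "epoch_series")) epochs <- list(epochs)
  days <- purrr::map_dfr(epochs, segment_days) |>
    apply_exclusions(sleep_logs, dst_events, off_wrist_max = off_wrist_max,
                     dst_exclusion_days = dst_exclusion_days,
                     drop_first_last = drop_first_last)
  nights <- score_nights(epochs, sleep_logs, threshold = threshold,
                         onset_run_minutes = onset_run_minutes)
  circ <- circadian_day_features(epochs, days, bin_minutes = bin_minutes)
  rows <- assemble_day_rows(circ, nights, sleep_logs)
  attr(rows, "qc_days") <- days
  rows
}

#' Run the classification analysis for one outcome
#'
#' Aggregates day rows to person level, selects the top-`k` features by
#' univariate F-score with correlation pruning, trains the boosted-tree
#' classifier under leave-one-subject-out cross-validation with
#' person-level probability averaging, evaluates it, and fits the
#' discriminant-validity OLS and the logistic model on averaged selected
#' features.
#'
#' @param rows Day-feature tibble ([derive_day_features()]).
#' @param outcomes Outcome tibble ([read_outcomes()]).
#' @param outcome One of `"ptsd_dx"`, `"pcl31"`, `"pcl38"`.
#' @param seed Integer seed for every stochastic step.
#' @param tune Tune hyperparameters per fold via [random_search()]
#'   (default `FALSE`: [default_gbt_params()]).
#' @param n_draws Random-search draws in tuned mode (default 25).
#' @param k,r_max Feature-selection settings (default top 3, prune at
#'   |r| >= 0.70).
#' @param selection_scope `"full_sample"` (default; selection on all
#'   persons, replicating the leaky-but-stable published design) or
#'   `"within_fold"` (re-selected on each training split).
#' @param iterations Bootstrap iterations for the AUC CI (default 2000).
#' @return A list of class `outcome_run`: `selection`, `loso`, `evaluation`,
#'   `validity_ols`, `logistic`, `outcome`.
#' @export
run_outcome_model <- function(rows, outcomes, outcome = "ptsd_dx", seed = 1,
                              tune = FALSE, n_draws = 25, k = 3, r_max = 0.70,
                              selection_scope = c("full_sample", "within_fold"),
                              iterations = 2000) {
  selection_scope <- match.arg(selection_scope)
  stopifnot(outcome %in% names(outcomes))
  oc <- outcomes[!is.na(outcomes[[outcome]]), ]
  rows <- rows[rows$participant_id %in% oc$participant_id, ]
  labels <- setNames(as.integer(oc[[outcome]]), oc$participant_id)

  person <- aggregate_person(rows)
  person_labels <- labels[person$participant_id]
  sel <- select_top_k(person, person_labels, k = k, r_max = r_max,
                      outcome_name = outcome)
  loso <- loso_cv(rows, labels, sel$accepted, seed = seed, tune = tune,
                  n_draws = n_draws,
                  select = if (selection_scope == "within_fold") {
                    list(k = k, r_max = r_max)
                  } else NULL)
  ev <- evaluate_model_run(loso, outcome_name = outcome,
                           iterations = iterations, seed = seed)
  oc2 <- oc[match(names(ev$person_scores), oc$participant_id), ]
  ols <- fit_discriminant_ols(unname(ev$person_scores), oc2[[outcome]],
                              oc2$nonptsd_dx, oc2$age)
  person2 <- person[match(oc2$participant_id, person$participant_id), ]
  logi <- fit_logistic(oc2[[outcome]], person2[sel$accepted])
  structure(list(outcome = outcome, selection = sel, loso = loso,
                 evaluation = ev, validity_ols = ols, logistic = logi),
            class = "outcome_run")
}

#' @export
print.outcome_run <- function(x, ...) {
  print(x$selection)
  print(x$evaluation)
  print(x$validity_ols)
  print(x$logistic)
  invisible(x)
}

#' Run the full pipeline for all three outcome definitions
#'
#' Convenience wrapper: clinician diagnosis plus the two probable-diagnosis
#' PCL-5 cutoffs (>= 31, >= 38), each via [run_outcome_model()], followed by
#' pairwise bootstrap AUC comparisons.
#'
#' @inheritParams run_outcome_model
#' @param outcomes_to_run Outcome columns to model.
#' @return A list of class `pipeline_result`: `runs` (named list of
#'   `outcome_run`), `auc_comparisons` tibble.
#' @export
run_ptsd_pipeline <- function(rows, outcomes,
                              outcomes_to_run = c("ptsd_dx", "pcl31", "pcl38"),
                              seed = 1, tune = FALSE, n_draws = 25,
                              iterations = 2000, ...) {
  runs <- lapply(outcomes_to_run, function(o) {
    run_outcome_model(rows, outcomes, outcome = o, seed = seed, tune = tune,
                      n_draws = n_draws, iterations = iterations, ...)
  })
  names(runs) <- outcomes_to_run
  pairs <- utils::combn(outcomes_to_run, 2, simplify = FALSE)
  cmp <- purrr::map_dfr(pairs, function(p) {
    a <- runs[[p[1]]]$evaluation; b <- runs[[p[2]]]$evaluation
    res <- bootstrap_auc_compare(a$person_scores, b$person_scores,
                                 a$labels, b$labels,
                                 iterations = iterations, seed = seed)
    dplyr::bind_cols(tibble::tibble(model_a = p[1], model_b = p[2]), res)
  })
  structure(list(runs = runs, auc_comparisons = cmp),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  for (r in x$runs) { print(r); cat("\n") }
  cat("bootstrap AUC comparisons:\n")
  print(x$auc_comparisons)
  invisible(x)
}

#' @export
glance.pipeline_result <- function(x, ...) {
  purrr::map_dfr(x$runs, ~ glance(.x$evaluation))
}
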