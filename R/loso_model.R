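# evaluate `code` under a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# fold-local integer seeds derived from one global seed, kept inside 32 bits
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483587)
}

#' Default hyperparameter search space
#'
#' Small-data-appropriate ranges for the gradient-boosted tree ensemble:
#' shallow trees, modest learning rates and round counts, optional row and
#' column subsampling.
#' @return Named list of candidate values per hyperparameter.
#' @export
default_search_space <- function() {
  list(max_depth = c(2L, 3L, 4L),
       eta = c(0.01, 0.05, 0.1, 0.3),
       nrounds = c(25L, 50L, 100L, 200L),
       subsample = c(0.7, 1.0),
       colsample_bytree = c(0.7, 1.0),
       min_child_weight = c(1, 5))
}

#' Default fixed hyperparameters (untuned mode)
#' @return Named list usable wherever a search draw is.
#' @export
default_gbt_params <- function() {
  list(max_depth = 3L, eta = 0.1, nrounds = 100L, subsample = 1.0,
       colsample_bytree = 1.0, min_child_weight = 1)
}

# fit one boosted-tree classifier; x: numeric matrix, y: 0/1
fit_gbt <- function(x, y, params, seed) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = params$max_depth,
                  eta = params$eta, subsample = params$subsample,
                  colsample_bytree = params$colsample_bytree,
                  min_child_weight = params$min_child_weight,
                  tree_method = "exact", nthread = 1, seed = seed),
    data = dtrain, nrounds = params$nrounds, verbose = 0
  )
}

#' Randomized hyperparameter search
#'
#' Draws `n_draws` parameter sets uniformly from `space` (deterministically
#' given `seed`) and returns the draw maximizing `score_fun(params)`. An
#' empty space returns [default_gbt_params()].
#'
#' @param space Named list of candidate values (see
#'   [default_search_space()]).
#' @param n_draws Number of random draws (>= 1).
#' @param seed Integer seed governing the draws.
#' @param score_fun Function of one parameter list returning a scalar score
#'   (larger is better).
#' @return The best-scoring parameter list, with attributes `score` and
#'   `draws` (tibble of all draws and scores).
#' @export
random_search <- function(space, n_draws, seed, score_fun) {
  if (length(space) == 0) return(default_gbt_params())
  stopifnot(n_draws >= 1)
  draws <- with_seed(seed, {
    lapply(seq_len(n_draws), function(i) {
      lapply(space, function(v) v[sample.int(length(v), 1)])
    })
  })
  scores <- vapply(draws, score_fun, numeric(1))
  best <- which.max(scores)
  out <- draws[[best]]
  attr(out, "score") <- scores[best]
  attr(out, "draws") <- tibble::tibble(
    draw = seq_len(n_draws),
    score = scores,
    params = purrr::map_chr(draws, ~ paste(names(.x), unlist(.x), sep = "=",
                                           collapse = " "))
  )
  out
}

# grouped k-fold assignment of participants, deterministic given seed
group_folds <- function(ids, k, seed) {
  ids <- unique(ids)
  with_seed(seed, {
    shuffled <- sample(ids)
    setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  })
}

# person-level AUC from grouped inner CV, used to score a search draw
inner_cv_score <- function(x, y, pid, params, k = 3, seed = 1) {
  fold_of <- group_folds(pid, k, seed)
  probs <- rep(NA_real_, length(y))
  for (f in seq_len(k)) {
    test <- fold_of[pid] == f
    if (!any(test) || length(unique(y[!test])) < 2) next
    bst <- fit_gbt(x[!test, , drop = FALSE], y[!test], params,
                   seed = derive_seed(seed, f))
    probs[test] <- predict(bst, xgboost::xgb.DMatrix(
      x[test, , drop = FALSE], nthread = 1))
  }
  ok <- !is.na(probs)
  person <- tapply(probs[ok], pid[ok], mean)
  person_y <- tapply(y[ok], pid[ok], unique)
  if (length(unique(person_y)) < 2) return(0.5)
  auc_mw(as.numeric(person), as.integer(person_y))
}

#' Leave-one-subject-out cross-validated boosted-tree classification
#'
#' One fold per participant: that participant's day rows are held out, a
#' Yeo-Johnson transform and a gradient-boosted tree classifier are fitted
#' on everyone else's day rows (labels inherited from the person), and the
#' held-out days are scored. Day probabilities are averaged within person to
#' give the person-level predicted probability. No held-out participant's
#' rows ever enter training; every fold carries a programmatic leakage
#' assertion.
#'
#' @param rows Day-feature tibble with `participant_id` and the model
#'   features.
#' @param labels Named 0/1 vector, one entry per participant.
#' @param features Character vector of feature columns to model.
#' @param seed Integer seed governing transforms, tree randomness and the
#'   hyperparameter search.
#' @param tune If `TRUE`, run [random_search()] with grouped 3-fold inner CV
#'   (by participant, scored by person-level AUC) inside every training
#'   split; if `FALSE` (default) use `params`.
#' @param params Fixed hyperparameters for the untuned mode
#'   (default [default_gbt_params()]).
#' @param space,n_draws Search space and number of draws for the tuned mode.
#' @param pool_transform If `TRUE`, fit the Yeo-Johnson transform on all
#'   rows (training + held-out pooled) instead of the training split only —
#'   a deliberately leaky variant kept for comparison with analyses that
#'   transformed before splitting.
#' @param select Optional list `list(k =, r_max =)`: re-run F-score feature
#'   selection on each training split's person-level aggregates (honest,
#'   leak-free selection), with `features` as the candidate set.
#' @return A list of class `loso_result`: `folds` (per-fold list with
#'   `held_out`, `day_probabilities`, `person_probability`, `booster`,
#'   `test_matrix`, `params`), `person_scores` tibble
#'   (`participant_id`, `probability`, `label`), `features`, `seed`.
#' @export
loso_cv <- function(rows, labels, features, seed = 1, tune = FALSE,
                    params = default_gbt_params(),
                    space = default_search_space(), n_draws = 25,
                    pool_transform = FALSE, select = NULL) {
  pids <- unique(rows$participant_id)
  if (length(pids) < 2) abort("leave-one-subject-out needs >= 2 participants.")
  if (!all(pids %in% names(labels))) abort("every participant needs a label.")
  labels <- labels[pids]
  if (length(unique(labels)) < 2) abort("both classes must be present.")

  folds <- lapply(seq_along(pids), function(i) {
    held <- pids[i]
    train <- rows[rows$participant_id != held, , drop = FALSE]
    test <- rows[rows$participant_id == held, , drop = FALSE]
    stopifnot(length(intersect(unique(train$participant_id),
                               unique(test$participant_id))) == 0)
    y_train <- unname(labels[train$participant_id])
    if (length(unique(y_train)) < 2) {
      return(list(held_out = held, invalid = TRUE))
    }
    fold_features <- if (is.null(select)) features else {
      pt <- aggregate_person(train, features)
      select_top_k(pt, labels[pt$participant_id], features = features,
                   k = select$k %||% 3, r_max = select$r_max %||% 0.70)$accepted
    }
    spec <- if (pool_transform) {
      yeo_johnson_fit(rows[fold_features], fold_features)
    } else {
      yeo_johnson_fit(train[fold_features], fold_features)
    }
    x_train <- as.matrix(yeo_johnson_apply(spec, train[fold_features]))
    x_test <- as.matrix(yeo_johnson_apply(spec, test[fold_features]))
    fold_seed <- derive_seed(seed, i)
    fold_params <- if (tune) {
      random_search(space, n_draws, fold_seed, function(p) {
        inner_cv_score(x_train, y_train, train$participant_id, p,
                       seed = fold_seed)
      })
    } else params
    bst <- fit_gbt(x_train, y_train, fold_params, seed = fold_seed)
    day_prob <- predict(bst, xgboost::xgb.DMatrix(x_test, nthread = 1))
    list(held_out = held, invalid = FALSE,
         train_ids = unique(train$participant_id),
         day_probabilities = as.numeric(day_prob),
         person_probability = mean(day_prob),
         booster = bst, test_matrix = x_test, params = fold_params)
  })
  valid <- !vapply(folds, `[[`, logical(1), "invalid")
  person_scores <- tibble::tibble(
    participant_id = pids[valid],
    probability = vapply(folds[valid], `[[`, numeric(1), "person_probability"),
    label = as.integer(labels[pids[valid]])
  )
  used <- unique(unlist(lapply(folds[valid], function(f)
    colnames(f$test_matrix))))
  structure(list(folds = folds, person_scores = person_scores,
                 features = used, seed = seed, tuned = tune),
            class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("LOSO run: %d folds, features: %s\n", length(x$folds),
              paste(x$features, collapse = ", ")))
  a <- auc_mw(x$person_scores$probability, x$person_scores$label)
  cat(sprintf("  person-level AUC %.3f\n", a))
  invisible(x)
}

#' @export
tidy.loso_result <- function(x, ...) x$person_scores

#' @export
glance.loso_result <- function(x, ...) {
  cm <- confusion_metrics(x$person_scores$probability, x$person_scores$label)
  dplyr::bind_cols(
    tibble::tibble(auc = auc_mw(x$person_scores$probability,
                                x$person_scores$label),
                   n_folds = length(x$folds)),
    cm
  )
}

#' Permutation null of the LOSO person-level AUC
#'
#' Re-runs the untuned LOSO pipeline with person labels randomly permuted
#' (seeded) and returns the person-level AUC of each permutation; a sound
#' pipeline has no residual signal, so the null AUCs centre on 0.5.
#'
#' @inheritParams loso_cv
#' @param n_perm Number of label permutations (default 20).
#' @return Numeric vector of permuted-label AUCs.
#' @export
loso_permutation_null <- function(rows, labels, features, n_perm = 20,
                                  seed = 1, params = default_gbt_params()) {
  pids <- names(labels)
  vapply(seq_len(n_perm), function(p) {
    perm <- with_seed(derive_seed(seed, p),
                      setNames(sample(unname(labels)), pids))
    res <- loso_cv(rows, perm, features, seed = derive_seed(seed, 1000 + p),
                   tune = FALSE, params = params)
    auc_mw(res$person_scores$probability, res$person_scores$label)
  }, numeric(1))
}
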