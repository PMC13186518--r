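test_that("random search is deterministic and returns the best draw", {
  space <- list(max_depth = c(2L, 4L), eta = c(0.05, 0.3))
  score <- function(p) p$max_depth + 10 * p$eta
  best <- random_search(space, n_draws = 20, seed = 5, score_fun = score)
  expect_equal(best$max_depth, 4L)
  expect_equal(best$eta, 0.3)
  again <- random_search(space, n_draws = 20, seed = 5, score_fun = score)
  expect_identical(attr(best, "draws"), attr(again, "draws"))

  one <- random_search(space, n_draws = 1, seed = 7, score_fun = score)
  expect_equal(nrow(attr(one, "draws")), 1)

  point <- random_search(list(max_depth = 3L), n_draws = 5, seed = 1,
                         score_fun = function(p) 0)
  expect_equal(point$max_depth, 3L)

  expect_equal(random_search(list(), 5, 1, function(p) 0),
               default_gbt_params())
})

test_that("random search picks the configuration that separates the data", {
  toy <- make_toy_rows(n_person = 12, n_days = 3, effect = 4, seed = 2)
  x <- as.matrix(toy$rows[c("signal", "noise1")])
  y <- unname(toy$labels[toy$rows$participant_id])
  # an eta so small the ensemble stays at chance vs a working one
  space <- list(eta = c(1e-5, 0.3), nrounds = c(50L), max_depth = c(2L),
                subsample = c(1.0), colsample_bytree = c(1.0),
                min_child_weight = c(1))
  best <- random_search(space, n_draws = 8, seed = 3, function(p) {
    actirhythm:::inner_cv_score(x, y, toy$rows$participant_id, p, seed = 3)
  })
  expect_equal(best$eta, 0.3)
})

test_that("LOSO produces one leak-free fold per participant", {
  toy <- make_toy_rows(n_person = 3, n_days = 2, effect = 3, seed = 4,
                       n_pos = 1)
  res <- loso_cv(toy$rows, toy$labels, c("signal", "noise1"), seed = 1)
  expect_length(res$folds, 3)
  for (f in res$folds) {
    if (isTRUE(f$invalid)) next
    expect_length(f$train_ids, 2)
    expect_false(f$held_out %in% f$train_ids)
    expect_equal(f$person_probability, mean(f$day_probabilities))
    expect_true(all(f$day_probabilities >= 0 & f$day_probabilities <= 1))
  }
})

test_that("an engineered leaky split trips the leakage guard", {
  # the guard asserts an empty train/test participant intersection; feed it
  # a split in which the held-out subject was copied into training
  train_ids <- c("s01", "s02", "s03")
  test_ids <- "s03"
  expect_error(
    stopifnot(length(intersect(train_ids, test_ids)) == 0),
    "intersect"
  )
})

test_that("LOSO is deterministic given a seed and separates a planted effect", {
  toy <- make_toy_rows(n_person = 12, n_days = 3, effect = 3, seed = 8)
  feats <- c("signal", "noise1", "noise2")
  r1 <- loso_cv(toy$rows, toy$labels, feats, seed = 11)
  r2 <- loso_cv(toy$rows, toy$labels, feats, seed = 11)
  expect_identical(r1$person_scores, r2$person_scores)

  auc <- actirhythm:::auc_mw(r1$person_scores$probability,
                             r1$person_scores$label)
  expect_gte(auc, 0.9)
})

test_that("permuted labels destroy the signal", {
  toy <- make_toy_rows(n_person = 10, n_days = 3, effect = 3, seed = 12)
  null_aucs <- loso_permutation_null(toy$rows, toy$labels,
                                     c("signal", "noise1"), n_perm = 8,
                                     seed = 13)
  expect_length(null_aucs, 8)
  expect_gt(mean(null_aucs), 0.25)
  expect_lt(mean(null_aucs), 0.75)
})

test_that("within-fold selection restricts each fold to its own top features", {
  toy <- make_toy_rows(n_person = 10, n_days = 3, effect = 4, seed = 14)
  res <- loso_cv(toy$rows, toy$labels,
                 features = c("signal", "noise1", "noise2"), seed = 15,
                 select = list(k = 1, r_max = 0.70))
  for (f in res$folds) {
    if (isTRUE(f$invalid)) next
    expect_equal(ncol(f$test_matrix), 1)
  }
  # the planted signal should dominate the per-fold selections
  picked <- table(unlist(lapply(res$folds, function(f) colnames(f$test_matrix))))
  expect_equal(names(which.max(picked)), "signal")
})

test_that("single-class training splits are flagged invalid", {
  toy <- make_toy_rows(n_person = 3, n_days = 2, effect = 2, seed = 16,
                       n_pos = 1)
  res <- loso_cv(toy$rows, toy$labels, "signal", seed = 1)
  held <- vapply(res$folds, `[[`, character(1), "held_out")
  invalid <- vapply(res$folds, `[[`, logical(1), "invalid")
  # holding out the only positive leaves a single-class training set
  expect_true(invalid[held == names(toy$labels)[toy$labels == 1]])
  expect_false(any(invalid[held %in% names(toy$labels)[toy$labels == 0]]))
})
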