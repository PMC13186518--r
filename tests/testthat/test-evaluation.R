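test_that("AUC follows the Mann-Whitney pair enumeration", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 0), iterations = 50)$auc, 1)
  expect_equal(roc_auc(c(0.8, 0.9, 0.3), c(1, 0, 0), iterations = 50)$auc, 0.5)
  expect_equal(roc_auc(rep(0.4, 10), rep(0:1, 5), iterations = 50)$auc, 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")

  # oracle equivalence: pROC trapezoidal AUC on random instances
  withr::with_seed(51, {
    for (i in 1:25) {
      n <- sample(10:40, 1)
      s <- runif(n)
      l <- rbinom(n, 1, 0.4)
      if (length(unique(l)) < 2) next
      oracle <- as.numeric(suppressMessages(pROC::auc(l, s, direction = "<")))
      expect_equal(roc_auc(s, l, iterations = 10)$auc, oracle,
                   tolerance = 1e-12)
    }
  })
})

test_that("bootstrap CI brackets the point estimate and tightens with signal", {
  withr::with_seed(53, {
    s <- c(rnorm(40, 1), rnorm(40, 0))
    l <- rep(c(1, 0), each = 40)
    r <- roc_auc(s, l, iterations = 1000, seed = 2)
    expect_true(r$ci_low <= r$auc && r$auc <= r$ci_high)
    expect_gt(r$ci_low, 0.5)
  })
})

test_that("confusion metrics reproduce printed worked examples", {
  # diagnosis-style counts: 5/8 sensitivity, 24/25 specificity
  m <- confusion_from_counts(tp = 5, fn = 3, tn = 24, fp = 1)
  expect_equal(m$accuracy, 29 / 33, tolerance = 1e-12)
  expect_equal(m$precision, 5 / 6, tolerance = 1e-12)
  expect_equal(m$f1, 2 * (5 / 6) * (5 / 8) / (5 / 6 + 5 / 8), tolerance = 1e-12)
  # 8/11 with 18/22
  m <- confusion_from_counts(tp = 8, fn = 3, tn = 18, fp = 4)
  expect_equal(m$accuracy, 26 / 33, tolerance = 1e-12)
  expect_equal(m$precision, 8 / 12, tolerance = 1e-12)
  expect_equal(round(m$f1, 2), 0.70)

  perfect <- confusion_metrics(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_true(all(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                   "precision", "f1")]) == 1))

  none <- confusion_metrics(c(0.1, 0.2, 0.3), c(1, 0, 0))
  expect_true(is.na(none$precision))
  expect_equal(none$f1, 0)
})

test_that("bootstrap AUC comparison is calibrated and symmetric", {
  withr::with_seed(59, {
    n <- 60
    ids <- sprintf("p%03d", 1:n)
    l <- setNames(rep(c(1, 0), each = n / 2), ids)
    s <- setNames(runif(n) + 0.5 * l, ids)
    same <- bootstrap_auc_compare(s, s, l, l, iterations = 400, seed = 3)
    expect_gte(same$p_value, 0.9)

    s2 <- setNames(runif(n), ids)                  # chance-level model
    ab <- bootstrap_auc_compare(s, s2, l, l, iterations = 400, seed = 4)
    ba <- bootstrap_auc_compare(s2, s, l, l, iterations = 400, seed = 4)
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$diff, -ba$diff)
  })
})

test_that("attributions satisfy local accuracy and concentrate on used features", {
  toy <- make_toy_rows(n_person = 8, n_days = 3, effect = 4, seed = 6)
  res <- loso_cv(toy$rows, toy$labels, c("signal", "noise1"), seed = 21,
                 params = list(max_depth = 2L, eta = 0.3, nrounds = 10L,
                               subsample = 1, colsample_bytree = 1,
                               min_child_weight = 1))
  a <- attribution_summary(res, tol = 1e-5)
  expect_lte(a$local_accuracy_max_error, 1e-5)
  expect_equal(names(a$mean_abs_shap)[1], "signal")
  expect_equal(names(a$mean_gain)[1], "signal")
  expect_true(all(diff(unname(a$mean_abs_shap)) <= 0))   # sorted descending
  expect_true(all(diff(unname(a$mean_gain)) <= 0))
  # a single-feature model holds all attribution mass
  res1 <- loso_cv(toy$rows, toy$labels, "signal", seed = 22)
  a1 <- attribution_summary(res1)
  expect_equal(unname(a1$mean_gain), 1)
  expect_gt(unname(a1$mean_abs_shap), 0)
})

test_that("a depth-1 single-split tree matches hand-enumerated attributions", {
  # two clusters on one feature: the tree has exactly one split and two
  # leaves, so each row's attribution is its leaf margin minus the
  # cover-weighted mean margin (the BIAS)
  x <- matrix(c(-2, -2, -2, 2, 2, 2), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- c(0, 0, 0, 1, 1, 1)
  bst <- actirhythm:::fit_gbt(x, y, list(max_depth = 1L, eta = 1, nrounds = 1L,
                                         subsample = 1, colsample_bytree = 1,
                                         min_child_weight = 0.1), seed = 1)
  dm <- xgboost::xgb.DMatrix(x, nthread = 1)
  contrib <- predict(bst, dm, predcontrib = TRUE)
  margin <- predict(bst, dm, outputmargin = TRUE)
  expect_equal(rowSums(contrib), margin, tolerance = 1e-6)
  bias <- contrib[, setdiff(colnames(contrib), "f")]
  expect_equal(unname(contrib[, "f"]), unname(margin - bias), tolerance = 1e-6)
  # equal covers: the base value is the midpoint of the two leaf margins
  expect_equal(unname(bias), rep(mean(unique(margin)), 6), tolerance = 1e-6)
})

test_that("model evaluation assembles AUC, confusion and attributions", {
  toy <- make_toy_rows(n_person = 10, n_days = 3, effect = 3, seed = 26)
  res <- loso_cv(toy$rows, toy$labels, c("signal", "noise1"), seed = 27)
  ev <- evaluate_model_run(res, outcome_name = "toy", iterations = 200,
                           seed = 28)
  expect_s3_class(ev, "model_run_result")
  expect_equal(sort(names(ev$person_scores)), sort(names(toy$labels)))
  g <- glance(ev)
  expect_true(all(c("auc", "accuracy", "f1") %in% names(g)))
  td <- tidy(ev)
  expect_equal(sort(td$feature), sort(c("signal", "noise1")))
})
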