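# Mann-Whitney AUC point estimate; ties count one half
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) abort("AUC needs both classes present.")
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC AUC with a bootstrap confidence interval
#'
#' Point estimate by the Mann-Whitney formulation (probability a random
#' positive outranks a random negative; ties count one half). The 95% CI
#' comes from a seeded percentile bootstrap that resamples persons with
#' replacement `iterations` times, skipping degenerate single-class
#' resamples.
#'
#' @param scores Person-level predicted probabilities.
#' @param labels 0/1 outcomes, same order.
#' @param iterations Bootstrap resamples (default 2000).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`.
#' @export
roc_auc <- function(scores, labels, iterations = 2000, seed = 1,
                    conf = 0.95) {
  labels <- as.integer(labels)
  est <- auc_mw(scores, labels)
  n <- length(scores)
  boots <- with_seed(seed, {
    vapply(seq_len(iterations), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) < 2) return(NA_real_)
      auc_mw(scores[idx], labels[idx])
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  alpha <- (1 - conf) / 2
  qs <- quantile(boots, c(alpha, 1 - alpha), names = FALSE, type = 7)
  tibble::tibble(auc = est, ci_low = qs[1], ci_high = qs[2])
}

#' Confusion metrics at a probability threshold
#'
#' Predicts positive when `score >= threshold` (default 0.5) and reports
#' accuracy, sensitivity, specificity, precision and the F1 score (harmonic
#' mean of precision and sensitivity). When no positives are predicted,
#' precision is undefined (`NA`) and F1 is 0 by convention.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 outcomes.
#' @param threshold Classification threshold (default 0.5).
#' @return One-row tibble: `tp`, `fn`, `tn`, `fp`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("confusion metrics need both classes.")
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.na(prec) || (prec + sens) == 0) 0 else {
    2 * prec * sens / (prec + sens)
  }
  tibble::tibble(tp = tp, fn = fn, tn = tn, fp = fp,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = sens, specificity = spec,
                 precision = prec, f1 = f1)
}

#' Confusion metrics from per-class counts
#'
#' Reconstructs a minimal score/label set realizing the given confusion
#' counts and evaluates it with [confusion_metrics()]; convenient for
#' checking a published confusion table (e.g. sensitivity 5/8 with
#' specificity 24/25).
#'
#' @param tp,fn,tn,fp Nonnegative integer cell counts.
#' @return As [confusion_metrics()].
#' @export
confusion_from_counts <- function(tp, fn, tn, fp) {
  scores <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  labels <- c(rep(1, tp), rep(1, fn), rep(0, tn), rep(0, fp))
  confusion_metrics(scores, labels, threshold = 0.5)
}

#' Bootstrap comparison of two models' AUCs
#'
#' Resamples participants with replacement `iterations` times — jointly
#' where the two cohorts share participants, so paired models are compared
#' on matched resamples — recomputes both AUCs per iteration, and returns
#' the two-sided p-value of the AUC difference,
#' `2 * min(P(diff <= 0), P(diff >= 0))` with the `(count + 1)/(iterations
#' + 1)` small-sample correction. Degenerate single-class resamples are
#' redrawn (capped retries).
#'
#' @param scores_a,scores_b Named probability vectors (names =
#'   participant ids).
#' @param labels_a,labels_b Named 0/1 vectors aligned to the scores.
#' @param iterations Bootstrap iterations (default 2000).
#' @param seed Integer seed.
#' @return One-row tibble: `auc_a`, `auc_b`, `diff`, `p_value`.
#' @export
bootstrap_auc_compare <- function(scores_a, scores_b, labels_a, labels_b,
                                  iterations = 2000, seed = 1) {
  ids_a <- names(scores_a); ids_b <- names(scores_b)
  if (is.null(ids_a) || is.null(ids_b)) abort("scores must be named by participant.")
  shared <- intersect(ids_a, ids_b)
  only_a <- setdiff(ids_a, shared); only_b <- setdiff(ids_b, shared)
  est_a <- auc_mw(scores_a, labels_a[ids_a])
  est_b <- auc_mw(scores_b, labels_b[ids_b])
  diffs <- with_seed(seed, {
    vapply(seq_len(iterations), function(b) {
      for (try in 1:100) {
        shared_r <- sample(shared, length(shared), replace = TRUE)
        a_ids <- c(shared_r, if (length(only_a))
          sample(only_a, length(only_a), replace = TRUE))
        b_ids <- c(shared_r, if (length(only_b))
          sample(only_b, length(only_b), replace = TRUE))
        la <- labels_a[a_ids]; lb <- labels_b[b_ids]
        if (length(unique(la)) == 2 && length(unique(lb)) == 2) {
          return(auc_mw(scores_a[a_ids], la) - auc_mw(scores_b[b_ids], lb))
        }
      }
      NA_real_
    }, numeric(1))
  })
  diffs <- diffs[!is.na(diffs)]
  m <- length(diffs)
  p_le <- (sum(diffs <= 0) + 1) / (m + 1)
  p_ge <- (sum(diffs >= 0) + 1) / (m + 1)
  tibble::tibble(auc_a = est_a, auc_b = est_b, diff = est_a - est_b,
                 p_value = min(1, 2 * min(p_le, p_ge)))
}

#' Per-feature attribution summaries of a LOSO run
#'
#' For each fold, exact additive tree-path attributions (SHAP values) are
#' computed on that fold's held-out rows; local accuracy — attributions plus
#' base value equal the model's margin output — holds to `tol` on every row
#' and is asserted. `mean_abs_shap` is the mean absolute attribution per
#' feature across all held-out rows and folds; `mean_gain` is the
#' normalized split-gain fraction per feature averaged over folds (features
#' never split on contribute 0). Both are returned sorted descending.
#'
#' @param result A [loso_cv()] result.
#' @param tol Local-accuracy tolerance (default 1e-5).
#' @return A list: `mean_abs_shap`, `mean_gain` (named, descending),
#'   `local_accuracy_max_error`.
#' @export
attribution_summary <- function(result, tol = 1e-5) {
  features <- result$features
  abs_sum <- setNames(numeric(length(features)), features)
  n_rows <- 0
  gain_mat <- NULL
  max_err <- 0
  for (fold in result$folds) {
    if (isTRUE(fold$invalid)) next
    dm <- xgboost::xgb.DMatrix(fold$test_matrix, nthread = 1)
    contrib <- predict(fold$booster, dm, predcontrib = TRUE)
    margin <- predict(fold$booster, dm, outputmargin = TRUE)
    err <- max(abs(rowSums(contrib) - margin))
    if (err > tol) {
      abort(sprintf("attribution local accuracy violated (max error %.2e).", err))
    }
    max_err <- max(max_err, err)
    cols <- intersect(colnames(contrib), features)   # last column is the bias
    abs_sum[cols] <- abs_sum[cols] + colSums(abs(contrib[, cols, drop = FALSE]))
    n_rows <- n_rows + nrow(contrib)
    # normalized split-gain fractions from the tree dump (robust to
    # ensembles that never split: those contribute all-zero gain)
    tr <- tryCatch(xgboost::xgb.model.dt.tree(model = fold$booster),
                   error = function(e) NULL)
    g <- setNames(numeric(length(features)), features)
    if (!is.null(tr)) {
      splits <- as.data.frame(tr)[tr$Feature != "Leaf", c("Feature", "Gain")]
      if (nrow(splits)) {
        tot <- tapply(splits$Gain, splits$Feature, sum)
        g[names(tot)] <- tot / sum(tot)
      }
    }
    gain_mat <- rbind(gain_mat, g)
  }
  mean_abs_shap <- sort(abs_sum / n_rows, decreasing = TRUE)
  mean_gain <- sort(colMeans(gain_mat), decreasing = TRUE)
  list(mean_abs_shap = mean_abs_shap, mean_gain = mean_gain,
       local_accuracy_max_error = max_err)
}

#' Full evaluation of a LOSO run
#'
#' Person-level AUC with bootstrap CI, confusion metrics at the threshold,
#' and attribution summaries, mirroring a standard performance table (AUC +
#' CI, accuracy, sensitivity, specificity, F1, precision, ranked SHAP and
#' information gain).
#'
#' @param result A [loso_cv()] result.
#' @param outcome_name Label for the report.
#' @param threshold Classification threshold (default 0.5).
#' @param iterations,seed Bootstrap settings for the AUC CI.
#' @return A list of class `model_run_result`.
#' @export
evaluate_model_run <- function(result, outcome_name = "outcome",
                               threshold = 0.5, iterations = 2000, seed = 1) {
  ps <- result$person_scores
  auc <- roc_auc(ps$probability, ps$label, iterations = iterations,
                 seed = seed)
  cm <- confusion_metrics(ps$probability, ps$label, threshold = threshold)
  attr_sum <- attribution_summary(result)
  structure(
    list(outcome_name = outcome_name,
         person_scores = setNames(ps$probability, ps$participant_id),
         labels = setNames(ps$label, ps$participant_id),
         auc = auc, confusion = cm,
         mean_abs_shap = attr_sum$mean_abs_shap,
         mean_gain = attr_sum$mean_gain),
    class = "model_run_result"
  )
}

#' @export
print.model_run_result <- function(x, ...) {
  cat("model run:", x$outcome_name, "\n")
  cat(sprintf("  AUC %.2f (95%% CI %.2f-%.2f)\n", x$auc$auc, x$auc$ci_low,
              x$auc$ci_high))
  with(x$confusion, cat(sprintf(
    "  accuracy %.2f  sensitivity %.2f (%d/%d)  specificity %.2f (%d/%d)\n  precision %.2f  F1 %.2f\n",
    accuracy, sensitivity, tp, tp + fn, specificity, tn, tn + fp,
    precision, f1)))
  cat("  mean |SHAP|:",
      paste(sprintf("%s=%.2f", names(x$mean_abs_shap), x$mean_abs_shap),
            collapse = "  "), "\n")
  cat("  mean gain:  ",
      paste(sprintf("%s=%.2f", names(x$mean_gain), x$mean_gain),
            collapse = "  "), "\n")
  invisible(x)
}

#' @export
tidy.model_run_result <- function(x, ...) {
  tibble::tibble(
    feature = names(x$mean_abs_shap),
    mean_abs_shap = unname(x$mean_abs_shap),
    mean_gain = unname(x$mean_gain[names(x$mean_abs_shap)])
  )
}

#' @export
glance.model_run_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(outcome = x$outcome_name),
    x$auc,
    x$confusion[c("accuracy", "sensitivity", "specificity", "precision", "f1")]
  )
}
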