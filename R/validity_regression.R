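#' Discriminant-validity linear regression
#'
#' Regresses person-level model-predicted probability scores on the PTSD
#' outcome flag while covarying for any current non-PTSD mental health
#' diagnosis (1 = present, 0 = absent) and age in years (uncentered, so the
#' intercept is the expected score of an undiagnosed person of age 0 on the
#' model's probability scale). A positive, significant outcome coefficient
#' alongside a null non-PTSD coefficient is the discriminant-validity
#' pattern: the scores track PTSD specifically, not mental health problems
#' generally. Inference uses the t distribution with `n - k - 1` degrees of
#' freedom.
#'
#' @param scores Person-level predicted probabilities.
#' @param outcome 0/1 PTSD outcome flag.
#' @param nonptsd 0/1 non-PTSD current-diagnosis flag.
#' @param age Age in years.
#' @return A list of class `ols_result`: `coefficients` tibble (`term`,
#'   `estimate`, `std_error`, `statistic`, `p_value`), `adj_r_squared`,
#'   `r_squared`, `n`, and the underlying `lm` fit.
#' @export
fit_discriminant_ols <- function(scores, outcome, nonptsd, age) {
  df <- tibble::tibble(score = scores, outcome = as.numeric(outcome),
                       nonptsd = as.numeric(nonptsd), age = as.numeric(age))
  df <- df[complete.cases(df), ]
  X <- cbind(1, df$outcome, df$nonptsd, df$age)
  if (qr(X)$rank < ncol(X)) {
    cols <- c("intercept", "outcome", "nonptsd", "age")
    drop_candidates <- cols[apply(X, 2, function(v) length(unique(v)) == 1)]
    abort(paste0("rank-deficient design; constant/collinear term(s): ",
                 paste(setdiff(drop_candidates, "intercept"), collapse = ", ")))
  }
  fit <- lm(score ~ outcome + nonptsd + age, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(coefficients = tibble::tibble(
           term = c("intercept", "outcome", "nonptsd_dx", "age"),
           estimate = unname(co[, 1]), std_error = unname(co[, 2]),
           statistic = unname(co[, 3]), p_value = unname(co[, 4])),
         adj_r_squared = sm$adj.r.squared, r_squared = sm$r.squared,
         n = nrow(df), fit = fit),
    class = "ols_result"
  )
}

#' @export
print.ols_result <- function(x, ...) {
  cat(sprintf("discriminant-validity OLS (n = %d, adjusted R^2 = %.2f)\n",
              x$n, x$adj_r_squared))
  co <- x$coefficients
  for (i in seq_len(nrow(co))) {
    cat(sprintf("  %-10s B = % .3f  SE = %.3f  t = % .2f  p = %.3g\n",
                co$term[i], co$estimate[i], co$std_error[i], co$statistic[i],
                co$p_value[i]))
  }
  invisible(x)
}

#' @export
tidy.ols_result <- function(x, ...) x$coefficients

#' @export
glance.ols_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
                 n = x$n)
}

#' Logistic regression of an outcome on averaged selected features
#'
#' Maximum-likelihood logistic fit of the 0/1 outcome on the within-person
#' averages of the selected features, with fit quality summarized by the
#' Nagelkerke pseudo-R-squared,
#' `(1 - exp(2*(L0 - L1)/n)) / (1 - exp(2*L0/n))`, which is 0 for the null
#' model and approaches 1 under perfect separation. Perfect or
#' quasi-perfect separation is detected (fitted probabilities numerically
#' at 0/1) and flagged; coefficients are still reported with a warning and
#' Nagelkerke R^2 is driven to 1.
#'
#' @param outcome 0/1 outcome flag, one per person.
#' @param feature_tbl Data frame of averaged selected features (persons in
#'   the same order); may have zero columns for the null model.
#' @return A list of class `logistic_result`: `coefficients` tibble,
#'   `log_likelihood`, `null_log_likelihood`, `nagelkerke_r2`, `separation`
#'   flag, `n`, and the `glm` fit.
#' @export
fit_logistic <- function(outcome, feature_tbl) {
  y <- as.integer(outcome)
  if (length(unique(y)) < 2) abort("logistic fit needs both classes present.")
  df <- tibble::tibble(.y = y)
  if (ncol(tibble::as_tibble(feature_tbl)) > 0) {
    df <- dplyr::bind_cols(df, tibble::as_tibble(feature_tbl))
  }
  fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
  null_fit <- glm(y ~ 1, family = binomial())
  l1 <- as.numeric(logLik(fit))
  l0 <- as.numeric(logLik(null_fit))
  n <- length(y)
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps) &&
    ncol(feature_tbl) > 0
  if (separation) {
    warn("(quasi-)perfect separation detected; coefficients are unstable.")
  }
  nk <- (1 - exp(2 * (l0 - l1) / n)) / (1 - exp(2 * l0 / n))
  nk <- min(1, max(0, nk))
  if (separation) nk <- 1
  sm <- summary(fit)$coefficients
  structure(
    list(coefficients = tibble::tibble(
           term = rownames(sm), estimate = unname(sm[, 1]),
           std_error = unname(sm[, 2]), statistic = unname(sm[, 3]),
           p_value = unname(sm[, 4])),
         log_likelihood = l1, null_log_likelihood = l0,
         nagelkerke_r2 = nk, separation = separation, n = n, fit = fit),
    class = "logistic_result"
  )
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("logistic fit (n = %d, Nagelkerke R^2 = %.2f%s)\n", x$n,
              x$nagelkerke_r2,
              if (x$separation) ", separation flagged" else ""))
  invisible(x)
}

#' @export
tidy.logistic_result <- function(x, ...) x$coefficients

#' @export
glance.logistic_result <- function(x, ...) {
  tibble::tibble(nagelkerke_r2 = x$nagelkerke_r2,
                 log_likelihood = x$log_likelihood,
                 null_log_likelihood = x$null_log_likelihood,
                 separation = x$separation, n = x$n)
}
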