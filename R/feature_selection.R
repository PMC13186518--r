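#' Aggregate day-level features to one row per participant
#'
#' The within-person arithmetic mean of each daily feature; feature
#' selection, the correlation pruning rule and the logistic validity models
#' all operate on these person-level aggregates.
#'
#' @param rows Day-feature tibble ([assemble_day_rows()]).
#' @param features Feature columns to aggregate (default [feature_names()]).
#' @return Tibble, one row per participant.
#' @export
aggregate_person <- function(rows, features = feature_names()) {
  features <- intersect(features, names(rows))
  rows |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(features),
                                   ~ mean(.x, na.rm = TRUE)),
                     n_days = dplyr::n(), .groups = "drop")
}

#' Univariate F-score of a feature against a binary outcome
#'
#' The one-way two-group ANOVA F statistic (between-group mean square over
#' within-group mean square), which for two groups equals the squared
#' pooled-variance two-sample t statistic. Perfect separation (zero
#' within-group variance with distinct group means) is guarded to a large
#' finite sentinel and flagged via the `"perfect_separation"` attribute.
#'
#' @param values Numeric feature values, one per person.
#' @param labels 0/1 outcome, same length.
#' @return The F statistic (>= 0).
#' @export
f_score <- function(values, labels) {
  labels <- as.integer(labels)
  ok <- is.finite(values) & !is.na(labels)
  values <- values[ok]; labels <- labels[ok]
  if (length(unique(labels)) < 2) abort("f_score needs both classes present.")
  n <- length(values)
  groups <- split(values, labels)
  k <- length(groups)
  grand <- mean(values)
  msb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1))) / (k - 1)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ssw == 0) {
    if (msb == 0) return(0)
    f <- 1e12
    attr(f, "perfect_separation") <- TRUE
    return(f)
  }
  msw <- ssw / (n - k)
  msb / msw
}

#' Select the top features by F-score with correlation pruning
#'
#' Ranks person-level aggregated features by descending univariate F-score
#' against the outcome (ties broken lexicographically by feature name) and
#' accepts them greedily, rejecting any candidate whose absolute Pearson
#' correlation with an already-accepted feature reaches `r_max`, until `k`
#' are accepted or the ranking is exhausted. This mirrors the common
#' small-sample practice of keeping a handful of weakly redundant markers —
#' e.g. a restfulness rating displacing a sleep-quality rating it correlates
#' with at r = 0.9.
#'
#' @param person_tbl Person-level table ([aggregate_person()]).
#' @param labels Named or positional 0/1 outcome vector aligned to
#'   `person_tbl` rows.
#' @param features Candidate feature columns (default: intersection of
#'   [feature_names()] with `person_tbl`).
#' @param k Number of features to accept (default 3).
#' @param r_max Pruning threshold on |Pearson r| (default 0.70; a candidate
#'   at or above it is rejected).
#' @param outcome_name Label stored in the report.
#' @return A list of class `selection_report`: `outcome_name`, `f_scores`
#'   (named, descending), `accepted`, `rejected_for_correlation` (tibble:
#'   `feature`, `conflicts_with`, `r`).
#' @export
select_top_k <- function(person_tbl, labels, features = NULL, k = 3,
                         r_max = 0.70, outcome_name = "outcome") {
  features <- features %||% intersect(feature_names(), names(person_tbl))
  if (length(features) < k) {
    warn("fewer candidate features than k.")
  }
  fs <- vapply(features, function(f) as.numeric(f_score(person_tbl[[f]], labels)),
               numeric(1))
  ord <- order(-fs, names(fs))
  fs <- fs[ord]
  accepted <- character()
  rejected <- tibble::tibble(feature = character(), conflicts_with = character(),
                             r = numeric())
  for (f in names(fs)) {
    if (length(accepted) >= k) break
    if (length(accepted)) {
      rr <- vapply(accepted, function(a) {
        stats::cor(person_tbl[[f]], person_tbl[[a]])
      }, numeric(1))
      if (any(abs(rr) >= r_max, na.rm = TRUE)) {
        j <- which.max(abs(rr))
        rejected <- dplyr::bind_rows(rejected, tibble::tibble(
          feature = f, conflicts_with = accepted[j], r = unname(rr[j])))
        next
      }
    }
    accepted <- c(accepted, f)
  }
  if (length(accepted) < k) {
    warn(paste0("only ", length(accepted), " acceptable features found."))
  }
  structure(list(outcome_name = outcome_name, f_scores = fs,
                 accepted = accepted, rejected_for_correlation = rejected),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("feature selection for outcome '", x$outcome_name, "'\n", sep = "")
  cat("  accepted:", paste(x$accepted, collapse = ", "), "\n")
  if (nrow(x$rejected_for_correlation)) {
    cat("  rejected for correlation:\n")
    for (i in seq_len(nrow(x$rejected_for_correlation))) {
      r <- x$rejected_for_correlation[i, ]
      cat(sprintf("    %s (r = %.2f with %s)\n", r$feature, r$r,
                  r$conflicts_with))
    }
  }
  invisible(x)
}

#' @export
tidy.selection_report <- function(x, ...) {
  tibble::tibble(
    feature = names(x$f_scores),
    f_score = unname(x$f_scores),
    rank = seq_along(x$f_scores),
    accepted = names(x$f_scores) %in% x$accepted
  )
}
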