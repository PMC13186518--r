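#' Double-plotted actogram of an epoch series
#'
#' The standard chronobiology display: one horizontal band per day, activity
#' drawn upward within the band, hours 0-24 on the x axis. Off-wrist epochs
#' are shaded.
#'
#' @param x An [epoch_series()].
#' @param bin_minutes Bin width for display smoothing (default 10).
#' @return A ggplot object.
#' @export
plot_actogram <- function(x, bin_minutes = 10) {
  len <- epoch_length(x)
  df <- tibble::tibble(
    date = as.Date(x$timestamp, tz = "UTC"),
    hour = (as.numeric(x$timestamp) %% 86400) / 3600,
    activity = ifelse(x$off_wrist, NA_real_, x$activity)
  )
  df$bin <- floor(df$hour * 60 / bin_minutes) * bin_minutes / 60
  agg <- df |>
    dplyr::group_by(.data$date, .data$bin) |>
    dplyr::summarise(activity = mean(.data$activity, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$bin, y = .data$activity)) +
    ggplot2::geom_col(width = bin_minutes / 60, fill = "grey20") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$date)) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 6), limits = c(0, 24)) +
    ggplot2::labs(x = "hour of day", y = "activity (counts/epoch)",
                  title = unique(x$participant_id)[1]) +
    ggplot2::theme_minimal() +
    ggplot2::theme(strip.text.y = ggplot2::element_text(angle = 0))
}

#' @describeIn plot_actogram Day profile with the fitted 24-h cosinor curve
#'   overlaid.
#' @param times,counts One day's epoch times (hours) and counts.
#' @export
plot_cosinor_fit <- function(times, counts) {
  fit <- fit_cosinor(times, counts)
  grid <- tibble::tibble(t = seq(0, 24, length.out = 241))
  grid$y <- fit$mesor +
    fit$amplitude * cos(2 * pi * (grid$t - fit$acrophase_time) / 24)
  ggplot2::ggplot(tibble::tibble(t = times, y = counts),
                  ggplot2::aes(.data$t, .data$y)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.4) +
    ggplot2::geom_line(data = grid, colour = "red", linewidth = 1) +
    ggplot2::labs(x = "hour of day", y = "activity",
                  subtitle = sprintf(
                    "mesor %.0f, amplitude %.0f, acrophase %.1f h, R² %.2f",
                    fit$mesor, fit$amplitude, fit$acrophase_time,
                    fit$r_squared)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.loso_result <- function(object, ...) {
  ps <- object$person_scores
  thr <- sort(unique(c(-Inf, ps$probability, Inf)), decreasing = TRUE)
  roc <- purrr::map_dfr(thr, function(t) {
    pred <- ps$probability >= t
    tibble::tibble(fpr = mean(pred[ps$label == 0]),
                   tpr = mean(pred[ps$label == 1]))
  })
  ggplot2::ggplot(roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step(linewidth = 1) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  subtitle = sprintf("person-level AUC %.2f",
                                     auc_mw(ps$probability, ps$label))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.model_run_result <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("mean_abs_shap", "mean_gain"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$value), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL, title = object$outcome_name) +
    ggplot2::theme_minimal()
}
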