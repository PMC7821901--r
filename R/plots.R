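# ggplot2 autoplot methods for the package's result objects.

#' Plot an event-triggered average
#'
#' Mean trace with a +/- SEM ribbon, aligned to the event onset (dashed line).
#'
#' @param object An `event_average`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.event_average <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_rel_s, y = .data$mean))
  if (object$sem_defined) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      fill = "grey70", alpha = 0.6)
  }
  p +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "time from event onset (s)", y = "dF/F",
                  title = sprintf("Event average (n = %d)", object$n_events)) +
    ggplot2::theme_minimal()
}

#' Plot a shuffle-test result
#'
#' Histograms of the shuffled max/min distributions with the observed values.
#'
#' @param object A `resampling_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resampling_result <- function(object, ...) {
  df <- tidy(object)
  obs <- tibble(statistic = c("max", "min"),
                value = c(object$observed_max, object$observed_min))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(data = obs, ggplot2::aes(xintercept = .data$value),
                        colour = "red") +
    ggplot2::facet_wrap(~statistic, scales = "free") +
    ggplot2::labs(x = "event-average extremum (dF/F)", y = "shuffles") +
    ggplot2::theme_minimal()
}

#' Plot decoder ROC curves
#'
#' One ROC per jack-knife split plus the chance diagonal.
#'
#' @param object A `decoding_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decoding_report <- function(object, ...) {
  df <- purrr::imap(object$roc, function(r, i) mutate(r, split = factor(i))) %>%
    list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$split)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Locomotor-state decoding (mean AUC = %.3f)",
                                  object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Plot an oriented-speed trace
#'
#' Speed over time coloured by locomotor state, with event onsets overlaid
#' when supplied.
#'
#' @param trace A speed trace from [oriented_speed()].
#' @param events Optional event-list tibble to overlay.
#' @return A ggplot.
#' @export
plot_speed_trace <- function(trace, events = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(x = .data$time_s, y = .data$speed_cms)) +
    ggplot2::geom_line(ggplot2::aes(group = 1, colour = .data$state)) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = "dotted") +
    ggplot2::labs(x = "time (s)", y = "oriented speed (cm/s)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    p <- p + ggplot2::geom_vline(data = events,
                                 ggplot2::aes(xintercept = .data$onset_s),
                                 alpha = 0.4, linetype = "dashed")
  }
  p
}
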