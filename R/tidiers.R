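# broom-style tidy()/glance() methods for the package's result objects.

#' @rdname event_average_tidiers
#' @title Tidiers for event-triggered averages
#' @description `tidy()` returns the per-frame mean and SEM; `glance()` the
#'   one-row summary (peak, trough, delta-T, event counts).
#' @param x An `event_average`.
#' @param ... Unused.
#' @export
tidy.event_average <- function(x, ...) {
  tibble(time_rel_s = x$time_rel_s, mean = x$mean, sem = x$sem)
}

#' @rdname event_average_tidiers
#' @export
glance.event_average <- function(x, ...) {
  tibble(n_events = x$n_events, n_dropped = x$n_dropped,
         peak = x$peak, trough = x$trough,
         dt_peak_s = x$dt_peak_s, dt_trough_s = x$dt_trough_s,
         sem_defined = x$sem_defined)
}

#' @rdname resampling_tidiers
#' @title Tidiers for shuffle-test results
#' @description `tidy()` returns the shuffled max/min distributions in long
#'   form; `glance()` the flags and observed extrema.
#' @param x A `resampling_result`.
#' @param ... Unused.
#' @export
tidy.resampling_result <- function(x, ...) {
  bind_rows(
    tibble(statistic = "max", value = x$shuffled_max),
    tibble(statistic = "min", value = x$shuffled_min)
  )
}

#' @rdname resampling_tidiers
#' @export
glance.resampling_result <- function(x, ...) {
  tibble(observed_max = x$observed_max, observed_min = x$observed_min,
         q_hi = x$q_hi, q_lo = x$q_lo,
         excited = x$excited, inhibited = x$inhibited,
         extremity_excited = x$extremity_excited,
         extremity_inhibited = x$extremity_inhibited,
         n_events = x$n_events, n_shuffles = x$n_shuffles,
         alpha = x$alpha, low_n = x$low_n)
}

#' @rdname activation_tidiers
#' @title Tidiers for activation-probability results
#' @description `tidy()` returns per-event coded flags; `glance()` the
#'   probability and baseline summary.
#' @param x An `activation_result`.
#' @param ... Unused.
#' @export
tidy.activation_result <- function(x, ...) x$per_event

#' @rdname activation_tidiers
#' @export
glance.activation_result <- function(x, ...) {
  tibble(probability = x$probability, n_events = x$n_events,
         n_coded = x$n_coded, baseline_sd = x$baseline_sd, k = x$k)
}

#' @rdname decoding_tidiers
#' @title Tidiers for decoding reports
#' @description `tidy()` returns per-split AUCs; `glance()` the averaged
#'   summary.
#' @param x A `decoding_report`.
#' @param ... Unused.
#' @export
tidy.decoding_report <- function(x, ...) {
  tibble(split = seq_along(x$auc), auc = x$auc)
}

#' @rdname decoding_tidiers
#' @export
glance.decoding_report <- function(x, ...) {
  tibble(mean_auc = x$mean_auc, n_splits = x$n_splits,
         n_cells = x$n_cells, n_frames = x$n_frames,
         n_resampled = x$n_resampled)
}

#' @rdname composition_tidiers
#' @title Tidiers for composition tests
#' @description `tidy()` returns the contingency table in long form;
#'   `glance()` the exact p-value.
#' @param x A `composition_test`.
#' @param ... Unused.
#' @export
tidy.composition_test <- function(x, ...) {
  as_tibble(as.data.frame(x$table)) %>%
    rename(n = "Freq")
}

#' @rdname composition_tidiers
#' @export
glance.composition_test <- function(x, ...) {
  tibble(p_value = x$p_value,
         n = sum(x$table),
         n_groups = nrow(x$table), n_classes = ncol(x$table))
}

#' @rdname pipeline_tidiers
#' @title Tidiers for pipeline results
#' @description `tidy()` returns the per-cell results table; `glance()` a
#'   one-row run summary.
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @export
tidy.pipeline_result <- function(x, ...) x$cell_results

#' @rdname pipeline_tidiers
#' @export
glance.pipeline_result <- function(x, ...) {
  stop_rows <- x$cell_results %>% filter(.data$behavior == "stop")
  tibble(
    n_cells = length(unique(x$cell_results$cell_id)),
    n_stops = sum(x$events$event == "stop"),
    n_starts = sum(x$events$event == "start"),
    n_grooming = sum(x$events$event == "grooming"),
    frac_stop_excited = mean(stop_rows$class == "excited"),
    frac_stop_inhibited = mean(stop_rows$class == "inhibited"),
    frac_stop_uncorrelated = mean(stop_rows$class == "uncorrelated"),
    composition_p = if (is.null(x$composition)) NA_real_ else x$composition$p_value,
    mean_auc = if (is.null(x$decoding)) NA_real_ else x$decoding$mean_auc
  )
}
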