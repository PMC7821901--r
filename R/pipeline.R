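# End-to-end orchestration: simulate (or load) -> detect events -> process
# traces -> shuffle tests -> classify -> composition test -> decode -> report.

#' Run the full analysis pipeline
#'
#' Runs every stage on a synthetic dataset (or one loaded from disk): event
#' detection on the oriented-speed trace, Gaussian smoothing of the dF/F
#' traces, per-cell shuffle tests for stops / starts / grooming, peri-event
#' peak statistics, stop-activation probability, cell classification,
#' medial-vs-lateral composition test, and population decoding of the
#' locomotor state. Every resolved parameter is recorded in the returned
#' `log` for provenance; with a fixed seed the whole bundle is reproducible.
#'
#' @param config A [sim_config()]; ignored when `input_dir` is given.
#' @param cells Ground-truth cell tibble ([default_cohort()] by default).
#' @param input_dir Optional directory written by [make_fixtures()] /
#'   [write_dataset()]; when given, data are read instead of simulated.
#' @param context Context label stored with the results
#'   (`"open_field"` or `"treadmill"`).
#' @param n_shuffles,alpha Parameters of [resampling_test()].
#' @param window Peri-event window ([event_window()]).
#' @param decode Run the population decoder (default `TRUE`).
#' @param seed Master seed for the analysis randomness (shuffles, splits).
#'   Defaults to `config$seed`.
#' @param output_dir Optional directory; when given, per-cell results, event
#'   lists, composition and decoding reports and the run log are written as
#'   CSV/JSON.
#' @return A `pipeline_result` list: `cell_results` (tibble, one row per cell
#'   x behaviour), `events`, `composition`, `decoding`, `unpredicted`,
#'   `dataset`, `log`.
#' @export
run_pipeline <- function(config = sim_config(), cells = default_cohort(),
                         input_dir = NULL, context = "open_field",
                         n_shuffles = 1000, alpha = 0.05,
                         window = event_window(), decode = TRUE,
                         seed = NULL, output_dir = NULL) {
  ds <- if (is.null(input_dir)) simulate_dataset(config, cells) else read_dataset(input_dir)
  config <- ds$config
  cells <- ds$cells
  seed <- seed %||% config$seed

  speed <- ds$behavior$speed
  cal_rate <- config$calcium_rate_hz
  detected <- bind_rows(
    detect_stops(speed),
    detect_long_stops(speed),
    detect_starts(speed)
  )
  grooming <- ds$events %>% filter(.data$event == "grooming")
  events <- bind_rows(detected, grooming) %>% arrange(.data$onset_s)

  smoothed <- gaussian_smooth(ds$traces)
  behaviors <- list(
    stop = events %>% filter(.data$event == "stop"),
    start = events %>% filter(.data$event == "start"),
    grooming = grooming
  )
  stops <- behaviors$stop

  rows <- list()
  for (i in seq_len(nrow(cells))) {
    id <- cells$cell_id[i]
    tr <- smoothed[[id]]
    for (b in names(behaviors)) {
      ev <- behaviors[[b]]
      if (nrow(ev) < 3) next
      res <- resampling_test(tr, ev, window = window, n_shuffles = n_shuffles,
                             alpha = alpha, rate_hz = cal_rate,
                             seed = seed + 7000L + i * 10L + match(b, names(behaviors)))
      eta <- event_triggered_average(tr, ev, window = window, rate_hz = cal_rate)
      ap <- if (b == "stop") {
        activation_probability(tr, ev, window = window, rate_hz = cal_rate)$probability
      } else NA_real_
      rows[[length(rows) + 1L]] <- tibble(
        cell_id = id, location = cells$location[i], context = context,
        behavior = b, class = suppressMessages(classify_cell(res)),
        excited = res$excited, inhibited = res$inhibited,
        n_events = res$n_events, peak = eta$peak, trough = eta$trough,
        dt_peak_s = eta$dt_peak_s, activation_prob = ap,
        true_class = cells$cell_class[i]
      )
    }
  }
  cell_results <- list_rbind(rows)

  composition <- tryCatch(
    composition_test(cell_results %>% filter(.data$behavior == "stop")),
    error = function(e) NULL
  )

  decoding <- NULL; unpredicted <- NULL
  if (decode) {
    states <- align_states(speed, smoothed$time_s)
    pm <- build_population_matrix(smoothed, states)
    if (!pm$untrainable) {
      decoding <- jackknife_train_eval(pm, seed = seed + 9999L)
      unpredicted <- unpredicted_stops(decoding, stops)
    }
  }

  log <- list(
    package_version = as.character(utils::packageVersion("locostop")),
    seed = seed, context = context, n_shuffles = n_shuffles, alpha = alpha,
    window_pre_s = window$pre_s, window_length_s = window$length_s,
    forward_thresh_cms = 3, backward_thresh_cms = -3,
    stop_min_immobility_s = 0.2, stop_min_run_s = 0.25, stop_min_avg_run_speed_cms = 5,
    long_stop_min_immobility_s = 3, long_stop_min_run_s = 0.1,
    start_min_stationary_s = 0.25, start_min_locomotion_s = 0.2, start_max_pre_speed_cms = 2,
    smooth_half_width_s = 0.15, deconvolution_tau_s = 0.5,
    activation_k_sd = 5, decode = decode, svm_cost = 1, n_splits = 5, train_frac = 0.8,
    config = unclass(config)
  )

  out <- structure(list(
    cell_results = cell_results, events = events, composition = composition,
    decoding = decoding, unpredicted = unpredicted, dataset = ds, log = log
  ), class = "pipeline_result")
  if (!is.null(output_dir)) write_pipeline_result(out, output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline result:", length(unique(x$cell_results$cell_id)), "cells,",
      nrow(x$events), "events\n")
  stop_rows <- x$cell_results %>% filter(.data$behavior == "stop")
  if (nrow(stop_rows)) {
    tb <- table(stop_rows$class)
    cat("  stop classes:", paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  }
  if (!is.null(x$composition)) {
    cat(sprintf("  composition test P = %.4g\n", x$composition$p_value))
  }
  if (!is.null(x$decoding)) cat(sprintf("  decoding mean AUC = %.3f\n", x$decoding$mean_auc))
  invisible(x)
}

# Deterministic JSON writer (sorted keys off, fixed precision).
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
}

#' Write a pipeline result bundle to disk
#'
#' Writes per-cell results and events as CSV, composition and decoding
#' reports and the run log as JSON. Outputs are deterministic for a fixed
#' seed and configuration.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$cell_results, file.path(dir, "cell_results.csv"))
  readr::write_csv(result$events, file.path(dir, "events.csv"))
  if (!is.null(result$composition)) {
    write_json_file(list(
      table = as.data.frame(result$composition$table),
      p_value = result$composition$p_value
    ), file.path(dir, "composition.json"))
  }
  if (!is.null(result$decoding)) {
    write_json_file(list(
      auc = result$decoding$auc, mean_auc = result$decoding$mean_auc,
      n_cells = result$decoding$n_cells, n_frames = result$decoding$n_frames,
      n_unpredicted_stops = if (is.null(result$unpredicted)) NA else nrow(result$unpredicted)
    ), file.path(dir, "decoding.json"))
  }
  write_json_file(result$log, file.path(dir, "run_log.json"))
  invisible(dir)
}

#' Write a synthetic dataset as plain-text files
#'
#' Writes the landmark track, speed trace, calcium traces, ground-truth
#' events and cell table as CSV and the configuration as JSON, with column
#' names and units documented in a schema file.
#'
#' @param ds A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory.
#' @param digits Significant digits for the trace CSVs.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir, digits = 6) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  num <- function(df) dplyr::mutate(df, across(dplyr::where(is.numeric), ~ signif(.x, digits)))
  readr::write_csv(num(ds$behavior$landmarks), file.path(dir, "landmarks.csv"))
  readr::write_csv(num(ds$behavior$speed), file.path(dir, "speed.csv"))
  readr::write_csv(num(ds$traces), file.path(dir, "traces.csv"))
  readr::write_csv(ds$events, file.path(dir, "events.csv"))
  readr::write_csv(ds$cells, file.path(dir, "cells.csv"))
  readr::write_csv(ds$behavior$schedule, file.path(dir, "schedule.csv"))
  write_json_file(unclass(ds$config), file.path(dir, "config.json"))
  writeLines(c(
    "landmarks.csv: frame (0-based), time_s (s), <landmark>_x/_y (cm) for left_ear, right_ear, spine",
    "speed.csv: frame, time_s (s), speed_cms (oriented speed, cm/s), state (forward/stationary/backward)",
    "traces.csv: time_s (s), one dF/F column per cell_id (20 Hz)",
    "events.csv: event (stop/long_stop/start/grooming), onset_s, onset_frame (0-based, behaviour clock), offset_s, provenance",
    "cells.csv: cell_id, cell_class, reliability_p, response_amp (a.u./s), sustained, location (medial/lateral)",
    "schedule.csv: state, start_s, end_s (s)",
    "config.json: simulation configuration (see ?sim_config)"
  ), file.path(dir, "SCHEMA.txt"))
  invisible(dir)
}

#' Read a synthetic dataset written by [write_dataset()]
#'
#' @param dir Directory containing the CSV/JSON files.
#' @return A `sim_dataset` list (landmarks re-derive the speed trace through
#'   [oriented_speed()], so loaded data follow the same path as simulated
#'   data).
#' @export
read_dataset <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  config <- sim_config(
    duration_s = cfg$duration_s, behavior_rate_hz = cfg$behavior_rate_hz,
    calcium_rate_hz = cfg$calcium_rate_hz,
    bout_duration_s = as.list(cfg$bout_duration_s),
    immobility_duration_s = as.list(cfg$immobility_duration_s),
    grooming_prob = cfg$grooming_prob, p_bout = cfg$p_bout,
    run_speed_cms = cfg$run_speed_cms, noise_sd = cfg$noise_sd,
    kernel_rise_s = cfg$kernel_rise_s, kernel_decay_s = cfg$kernel_decay_s,
    ramp_s = cfg$ramp_s, seed = cfg$seed
  )
  landmarks <- readr::read_csv(file.path(dir, "landmarks.csv"), show_col_types = FALSE)
  speed <- oriented_speed(landmarks)
  events <- readr::read_csv(file.path(dir, "events.csv"), show_col_types = FALSE)
  schedule <- readr::read_csv(file.path(dir, "schedule.csv"), show_col_types = FALSE)
  traces <- readr::read_csv(file.path(dir, "traces.csv"), show_col_types = FALSE)
  attr(traces, "rate_hz") <- config$calcium_rate_hz
  cells <- readr::read_csv(file.path(dir, "cells.csv"), show_col_types = FALSE)
  behavior <- structure(list(schedule = schedule, landmarks = landmarks,
                             speed = speed, events = events, config = config),
                        class = "behavior_sim")
  structure(list(behavior = behavior, traces = traces, cells = cells,
                 events = events, config = config),
            class = "sim_dataset")
}

#' Generate a packaged synthetic fixture
#'
#' Writes a small, fully reproducible dataset for tests and examples. The
#' `tiny` scale (60 s, 4 cells spanning the planted classes) runs the whole
#' pipeline in seconds; `default` (300 s, 12 cells) exercises it at a more
#' realistic size.
#'
#' @param dir Output directory.
#' @param scale `"tiny"` or `"default"`.
#' @param seed Seed stored in the config (default 42).
#' @return `dir`, invisibly; the dataset is written with [write_dataset()].
#' @export
make_fixtures <- function(dir, scale = c("tiny", "default"), seed = 42L) {
  scale <- match.arg(scale)
  if (scale == "tiny") {
    # immobility >= 3.2 s makes every stop a long stop, and grooming_prob = 1
    # puts a grooming epoch in every immobility period, so the tiny fixture
    # is guaranteed to contain every event type
    config <- sim_config(
      duration_s = 60, seed = seed,
      bout_duration_s = list(mean = 3, min = 1.5, max = 6),
      immobility_duration_s = list(mean = 4, min = 3.2, max = 8),
      grooming_prob = 1
    )
    cells <- bind_rows(
      ground_truth_cell("cell_01", "stop_excited", location = "lateral"),
      ground_truth_cell("cell_02", "stop_inhibited", location = "medial"),
      ground_truth_cell("cell_03", "grooming_excited", location = "lateral"),
      ground_truth_cell("cell_04", "uncorrelated", location = "medial")
    )
  } else {
    config <- sim_config(duration_s = 300, seed = seed, grooming_prob = 0.3)
    cells <- default_cohort(12)
  }
  ds <- simulate_dataset(config, cells)
  write_dataset(ds, dir)
  invisible(dir)
}
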