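# Behavioural side of the pipeline: oriented speed from landmark tracking,
# rule-based detection of stop / long-stop / start events, and manual
# annotations.

#' Oriented locomotor speed from body landmarks
#'
#' Computes the signed locomotor speed along the body axis. The body
#' orientation at each frame is the unit vector from the spine point to the
#' midpoint between the two ears; the speed is the frame-to-frame displacement
#' of the ear midpoint projected onto that vector, divided by the frame
#' interval. Positive values are forward movement, negative backward.
#'
#' Frames with a degenerate orientation (ears coinciding with the spine point)
#' carry the most recent well-defined orientation. The first frame copies the
#' second frame's speed so the output has the same length as the input.
#'
#' @param track A landmark table with columns `time_s`, `left_ear_x`,
#'   `left_ear_y`, `right_ear_x`, `right_ear_y`, `spine_x`, `spine_y`
#'   (coordinates in cm, time in seconds, uniform sampling).
#' @param forward_thresh,backward_thresh Speed thresholds (cm/s) passed to
#'   [classify_state()].
#' @return A speed-trace tibble with columns `frame` (0-based), `time_s`,
#'   `speed_cms` and `state` (`"forward"`, `"stationary"` or `"backward"`),
#'   carrying the sampling rate in attribute `rate_hz`.
#' @seealso [classify_state()], [detect_stops()], [detect_starts()]
#' @export
#' @examples
#' tr <- tibble::tibble(
#'   time_s = seq(0, 1, by = 0.05),
#'   left_ear_x = seq(0, 4, by = 0.2), left_ear_y = 0.75,
#'   right_ear_x = seq(0, 4, by = 0.2), right_ear_y = -0.75,
#'   spine_x = seq(0, 4, by = 0.2) - 2, spine_y = 0
#' )
#' oriented_speed(tr)
oriented_speed <- function(track, forward_thresh = 3, backward_thresh = -3) {
  needed <- c("time_s", "left_ear_x", "left_ear_y", "right_ear_x",
              "right_ear_y", "spine_x", "spine_y")
  missing_cols <- setdiff(needed, names(track))
  if (length(missing_cols)) {
    stop("track is missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(track)
  if (n < 2) stop("track needs at least 2 frames", call. = FALSE)
  coords <- as.matrix(track[, setdiff(needed, "time_s")])
  if (any(!is.finite(coords))) stop("landmark coordinates must be finite", call. = FALSE)
  rate <- infer_rate(track$time_s)
  dt <- 1 / rate

  mid_x <- (track$left_ear_x + track$right_ear_x) / 2
  mid_y <- (track$left_ear_y + track$right_ear_y) / 2
  hx <- mid_x - track$spine_x
  hy <- mid_y - track$spine_y
  nrm <- sqrt(hx^2 + hy^2)
  ok <- nrm > 1e-9
  if (!any(ok)) stop("body orientation is degenerate at every frame", call. = FALSE)
  # carry the last well-defined orientation through degenerate frames
  last_ok <- cummax(ifelse(ok, seq_len(n), 0L))
  first_valid <- which(ok)[1]
  last_ok[last_ok == 0L] <- first_valid
  ux <- (hx / nrm)[last_ok]
  uy <- (hy / nrm)[last_ok]

  speed <- c(NA_real_, (diff(mid_x) * ux[-1] + diff(mid_y) * uy[-1]) / dt)
  speed[1] <- speed[2]

  out <- tibble(
    frame = seq_len(n) - 1L,
    time_s = track$time_s,
    speed_cms = speed,
    state = classify_state(speed, forward_thresh, backward_thresh)
  )
  attr(out, "rate_hz") <- rate
  out
}

#' Classify the locomotor state from oriented speed
#'
#' Forward locomotion is speed strictly above `forward_thresh`, backward
#' locomotion strictly below `backward_thresh`; everything in between is
#' immobility (`"stationary"`). The default +/-3 cm/s threshold suits
#' freely-moving mice tracked at 20-50 Hz.
#'
#' @param speed_cms Numeric vector of oriented speeds (cm/s).
#' @param forward_thresh,backward_thresh Thresholds in cm/s.
#' @return Character vector of states.
#' @export
classify_state <- function(speed_cms, forward_thresh = 3, backward_thresh = -3) {
  if (any(!is.finite(speed_cms))) stop("speed must be finite", call. = FALSE)
  if (backward_thresh >= forward_thresh) stop("backward_thresh must be below forward_thresh", call. = FALSE)
  dplyr::case_when(
    speed_cms > forward_thresh ~ "forward",
    speed_cms < backward_thresh ~ "backward",
    .default = "stationary"
  )
}

# Shared transition detector. Scans the run-length encoding of the state
# sequence for `from`-runs of at least min_pre frames followed by `to`-runs of
# at least min_post frames; optional speed conditions are evaluated on the
# frames of the preceding run.
detect_transitions <- function(trace, from, to, min_pre_f, min_post_f,
                               pre_speed_fun = NULL, valid_periods = NULL,
                               event = "stop") {
  stopifnot(is.data.frame(trace), all(c("time_s", "speed_cms", "state") %in% names(trace)))
  vp <- check_valid_periods(valid_periods)
  out <- new_event_list()
  if (nrow(trace) == 0) return(out)
  r <- rle(trace$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$lengths)
  onsets <- integer(0)
  offsets <- numeric(0)
  for (i in seq_len(k - 1L)) {
    if (r$values[i] != from || r$values[i + 1L] != to) next
    if (r$lengths[i] < min_pre_f || r$lengths[i + 1L] < min_post_f) next
    pre_idx <- starts[i]:ends[i]
    if (!is.null(pre_speed_fun) && !pre_speed_fun(trace$speed_cms[pre_idx])) next
    onsets <- c(onsets, starts[i + 1L])
    # offset = end of the `to` run (time of the first frame after it, NA at end)
    nxt <- ends[i + 1L] + 1L
    offsets <- c(offsets, if (nxt <= nrow(trace)) trace$time_s[nxt] else NA_real_)
  }
  if (!length(onsets)) return(out)
  ev <- new_event_list(
    event = rep(event, length(onsets)),
    onset_s = trace$time_s[onsets],
    onset_frame = onsets - 1L,
    offset_s = offsets,
    provenance = rep("detected", length(onsets))
  )
  if (!is.null(vp)) ev <- ev[in_valid_periods(ev$onset_s, vp), ]
  ev
}

#' Detect locomotor stops
#'
#' A stop is the onset of an immobility period lasting at least
#' `min_immobility` seconds that follows a forward run of at least `min_run`
#' seconds whose average speed exceeds `min_avg_run_speed` (the latter selects
#' genuine supra-threshold runs). The event onset is the first stationary
#' frame. Durations are converted to whole frames with round-half-up and all
#' criteria are evaluated at frame resolution.
#'
#' @param trace A speed trace as returned by [oriented_speed()].
#' @param min_immobility Minimum immobility duration (s), default 0.2.
#' @param min_run Minimum preceding run duration (s), default 0.25.
#' @param min_avg_run_speed Minimum average speed (cm/s) over the preceding
#'   run, default 5; `NULL` disables the condition.
#' @param valid_periods Optional tibble (`start_s`, `end_s`) restricting
#'   analysis; only events with onset inside a period are returned (e.g.
#'   treadmill-engaged periods).
#' @return An event-list tibble (`event`, `onset_s`, `onset_frame`,
#'   `offset_s`, `provenance`).
#' @export
detect_stops <- function(trace, min_immobility = 0.2, min_run = 0.25,
                         min_avg_run_speed = 5, valid_periods = NULL) {
  rate <- attr(trace, "rate_hz") %||% infer_rate(trace$time_s)
  fun <- if (is.null(min_avg_run_speed)) NULL else function(v) mean(v) > min_avg_run_speed
  detect_transitions(
    trace, "forward", "stationary",
    min_pre_f = max(1L, sec_to_frames(min_run, rate)),
    min_post_f = max(1L, sec_to_frames(min_immobility, rate)),
    pre_speed_fun = fun, valid_periods = valid_periods, event = "stop"
  )
}

#' Detect long locomotor stops
#'
#' Variant of [detect_stops()] for sustained arrests: immobility must last at
#' least 3 s, the preceding run only 100 ms, and no average-speed condition is
#' applied (this keeps more events, at the cost of admitting slower runs).
#'
#' @inheritParams detect_stops
#' @param min_immobility Minimum immobility duration (s), default 3.
#' @param min_run Minimum preceding run duration (s), default 0.1.
#' @return An event-list tibble with `event = "long_stop"`.
#' @export
detect_long_stops <- function(trace, min_immobility = 3, min_run = 0.1,
                              valid_periods = NULL) {
  rate <- attr(trace, "rate_hz") %||% infer_rate(trace$time_s)
  detect_transitions(
    trace, "forward", "stationary",
    min_pre_f = max(1L, sec_to_frames(min_run, rate)),
    min_post_f = max(1L, sec_to_frames(min_immobility, rate)),
    pre_speed_fun = NULL, valid_periods = valid_periods, event = "long_stop"
  )
}

#' Detect locomotor starts
#'
#' A start is the first forward frame of a locomotion period lasting at least
#' `min_locomotion` seconds that follows a stationary period of at least
#' `min_stationary` seconds whose mean absolute speed is below
#' `max_pre_speed` (the animal must have been genuinely still).
#'
#' @inheritParams detect_stops
#' @param min_stationary Minimum stationary duration (s), default 0.25.
#' @param min_locomotion Minimum locomotion duration (s), default 0.2.
#' @param max_pre_speed Maximum mean absolute speed (cm/s) during the
#'   stationary period, default 2.
#' @return An event-list tibble with `event = "start"`.
#' @export
detect_starts <- function(trace, min_stationary = 0.25, min_locomotion = 0.2,
                          max_pre_speed = 2, valid_periods = NULL) {
  rate <- attr(trace, "rate_hz") %||% infer_rate(trace$time_s)
  detect_transitions(
    trace, "stationary", "forward",
    min_pre_f = max(1L, sec_to_frames(min_stationary, rate)),
    min_post_f = max(1L, sec_to_frames(min_locomotion, rate)),
    pre_speed_fun = function(v) mean(abs(v)) < max_pre_speed,
    valid_periods = valid_periods, event = "start"
  )
}

#' Read manually annotated behavioural events
#'
#' Reads a CSV of manual annotations (e.g. treadmill stops scored frame by
#' frame, or grooming epochs) and returns a validated event list. The file
#' must have columns `type` (or `event`) and `onset_s`, optionally `offset_s`.
#'
#' @param file Path to the annotation CSV.
#' @param recording_end_s Duration of the recording (s); onsets outside
#'   `[0, recording_end_s]` are rejected.
#' @param rate_hz Optional sampling rate used to fill `onset_frame`
#'   (round-half-up); left `NA` when omitted.
#' @return An event-list tibble with `provenance = "annotated"`.
#' @export
read_annotations <- function(file, recording_end_s, rate_hz = NULL) {
  stopifnot(is.numeric(recording_end_s), recording_end_s > 0)
  df <- readr::read_csv(file, show_col_types = FALSE)
  if (nrow(df) == 0) return(new_event_list())
  if ("event" %in% names(df) && !"type" %in% names(df)) df$type <- df$event
  if (!all(c("type", "onset_s") %in% names(df))) {
    stop("annotation file needs columns type (or event) and onset_s", call. = FALSE)
  }
  bad_type <- which(!df$type %in% event_types)
  if (length(bad_type)) {
    stop("row ", bad_type[1], ": unknown event type '", df$type[bad_type[1]],
         "' (expected one of ", paste(event_types, collapse = ", "), ")", call. = FALSE)
  }
  onset <- suppressWarnings(as.numeric(df$onset_s))
  bad_num <- which(!is.finite(onset))
  if (length(bad_num)) stop("row ", bad_num[1], ": onset_s is not a finite number", call. = FALSE)
  oob <- which(onset < 0 | onset > recording_end_s)
  if (length(oob)) {
    stop("row ", oob[1], ": onset ", onset[oob[1]], " s is outside the recording [0, ",
         recording_end_s, "] s", call. = FALSE)
  }
  offset <- if ("offset_s" %in% names(df)) suppressWarnings(as.numeric(df$offset_s)) else rep(NA_real_, nrow(df))
  new_event_list(
    event = df$type,
    onset_s = onset,
    onset_frame = if (is.null(rate_hz)) rep(NA_integer_, nrow(df)) else sec_to_frames(onset, rate_hz),
    offset_s = offset,
    provenance = rep("annotated", nrow(df))
  ) %>% arrange(.data$onset_s)
}

#' Map behavioural states onto another clock
#'
#' Behaviour video is often acquired at 50 Hz while calcium imaging runs at
#' 20 Hz, with hardware-triggered shared start. This maps per-frame state
#' labels onto target timestamps by nearest-timestamp lookup.
#'
#' @param trace A speed trace ([oriented_speed()] output).
#' @param target_time_s Timestamps of the target clock (s).
#' @return Character vector of states, one per target timestamp.
#' @export
align_states <- function(trace, target_time_s) {
  idx <- round(approx(trace$time_s, seq_len(nrow(trace)), xout = target_time_s, rule = 2)$y)
  trace$state[pmin(pmax(idx, 1L), nrow(trace))]
}

#' Per-event pre-stop kinematics
#'
#' For each event, summarises the locomotion that preceded it: mean speed and
#' peak deceleration over the `pre_s` seconds before onset, and the duration
#' of the immediately preceding forward run. Used to relate per-event response
#' amplitudes to movement kinematics.
#'
#' @param trace A speed trace.
#' @param events An event-list tibble.
#' @param pre_s Look-back window (s), default 1.
#' @return Tibble with one row per event: `onset_s`, `pre_speed_cms`,
#'   `peak_decel_cms2`, `run_duration_s`.
#' @export
stop_kinematics <- function(trace, events, pre_s = 1) {
  rate <- attr(trace, "rate_hz") %||% infer_rate(trace$time_s)
  dt <- 1 / rate
  npre <- max(2L, sec_to_frames(pre_s, rate))
  r <- rle(trace$state)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  purrr::map(seq_len(nrow(events)), function(i) {
    on <- events$onset_frame[i] + 1L
    idx <- max(1L, on - npre):(on - 1L)
    v <- trace$speed_cms[idx]
    # preceding forward run duration
    prev <- which(run_end < on & r$values == "forward")
    rd <- if (length(prev)) r$lengths[tail(prev, 1)] * dt else NA_real_
    tibble(
      onset_s = events$onset_s[i],
      pre_speed_cms = mean(v),
      peak_decel_cms2 = if (length(v) > 1) max(-diff(v)) / dt else NA_real_,
      run_duration_s = rd
    )
  }) %>% list_rbind()
}
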