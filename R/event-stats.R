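# Per-cell event statistics: event-triggered averages, the shuffle
# (resampling) significance test, per-event activation probability, and
# correlations between response amplitude and movement kinematics.

#' Peri-event analysis window
#'
#' Defines the half-open window `[onset - pre_s, onset - pre_s + length_s)`
#' used by all peri-event statistics. Defaults: 1.5 s starting 0.25 s before
#' the event (stops, starts and grooming onsets); use `length_s = 4.25` for
#' sustained grooming activity.
#'
#' @param pre_s Time before the event onset included in the window (s).
#' @param length_s Total window length (s).
#' @return An `event_window` list.
#' @export
event_window <- function(pre_s = 0.25, length_s = 1.5) {
  stopifnot(pre_s >= 0, length_s > pre_s)
  structure(list(pre_s = pre_s, length_s = length_s), class = "event_window")
}

# Window geometry in frames for a given rate.
window_frames <- function(window, rate_hz) {
  list(pre_f = sec_to_frames(window$pre_s, rate_hz),
       len_f = max(2L, sec_to_frames(window$length_s, rate_hz)))
}

# Onset frames (0-based) from an event list, derived from onset_s when the
# frame column is absent/NA, on the trace's clock.
event_onset_frames <- function(events, rate_hz) {
  if (is.numeric(events) && is.null(dim(events))) {
    return(sec_to_frames(events, rate_hz))
  }
  stopifnot(is.data.frame(events))
  if ("onset_s" %in% names(events)) return(sec_to_frames(events$onset_s, rate_hz))
  stop("events must have an onset_s column", call. = FALSE)
}

# Segment matrix (events x frames) for onsets with full coverage.
event_segments <- function(values, onsets0, pre_f, len_f) {
  start <- onsets0 + 1L - pre_f
  keep <- start >= 1L & (start + len_f - 1L) <= length(values)
  start <- start[keep]
  if (!length(start)) {
    return(list(seg = matrix(numeric(0), 0, len_f), n_dropped = sum(!keep)))
  }
  idx <- outer(start, 0:(len_f - 1L), "+")
  list(seg = matrix(values[idx], nrow = length(start)), n_dropped = sum(!keep))
}

#' Event-triggered average of a calcium trace
#'
#' Averages trace segments aligned to event onsets within a peri-event
#' window, reporting the mean and SEM per frame together with the peak and
#' trough of the mean and the time from the event onset to the peak
#' (delta-T). Events whose window is not fully covered by the recording are
#' dropped and counted.
#'
#' @param trace Numeric vector (with `rate_hz`) or trace tibble
#'   (`time_s`, value column).
#' @param events Event-list tibble or numeric vector of onset times (s).
#' @param window An [event_window()].
#' @param rate_hz Sampling rate for bare-vector traces.
#' @return An `event_average` object; see [tidy()] / [glance()] /
#'   [autoplot()] methods.
#' @export
event_triggered_average <- function(trace, events, window = event_window(),
                                    rate_hz = NULL) {
  tr <- as_trace(trace, rate_hz)
  wf <- window_frames(window, tr$rate_hz)
  onsets0 <- event_onset_frames(events, tr$rate_hz)
  es <- event_segments(tr$values, onsets0, wf$pre_f, wf$len_f)
  n_ev <- nrow(es$seg)
  if (n_ev == 0) stop("no event has a fully covered window", call. = FALSE)
  mu <- colMeans(es$seg)
  sem <- if (n_ev > 1) apply(es$seg, 2, sd) / sqrt(n_ev) else rep(NA_real_, wf$len_f)
  dt <- 1 / tr$rate_hz
  time_rel <- (seq_len(wf$len_f) - 1L - wf$pre_f) * dt
  structure(list(
    window = window, rate_hz = tr$rate_hz, time_rel_s = time_rel,
    mean = mu, sem = sem, n_events = n_ev, n_dropped = es$n_dropped,
    sem_defined = n_ev > 1,
    peak = max(mu), trough = min(mu),
    dt_peak_s = time_rel[which.max(mu)], dt_trough_s = time_rel[which.min(mu)]
  ), class = "event_average")
}

#' @export
print.event_average <- function(x, ...) {
  cat("Event-triggered average:", x$n_events, "events",
      sprintf("(%d dropped)", x$n_dropped), "\n")
  cat(sprintf("  peak %.4f at %+.3f s, trough %.4f at %+.3f s\n",
              x$peak, x$dt_peak_s, x$trough, x$dt_trough_s))
  invisible(x)
}

#' Shuffle test for peri-event excitation / inhibition
#'
#' Tests whether the peak (and trough) of the event-triggered average is more
#' extreme than expected for randomly placed events. Each shuffle draws the
#' same number of pseudo-onsets uniformly among the frames allowed by
#' `valid_periods` (full window coverage enforced, no minimum separation) and
#' recomputes the event-average maximum and minimum. The cell is flagged
#' excited if the observed maximum strictly exceeds the `1 - alpha` quantile
#' of shuffled maxima, inhibited if the observed minimum falls strictly below
#' the `alpha` quantile of shuffled minima (two one-sided tests; ties are not
#' significant; type-7 quantiles).
#'
#' @inheritParams event_triggered_average
#' @param valid_periods Optional tibble (`start_s`, `end_s`): periods in which
#'   pseudo-onsets may fall (e.g. treadmill-engaged time). Default: the whole
#'   recording.
#' @param n_shuffles Number of shuffles (default 1000, minimum 100).
#' @param alpha Tail probability per direction (default 0.05; use 0.025 for a
#'   Bonferroni-style split across the two directions).
#' @param seed Seed for the pseudo-onset draws.
#' @return A `resampling_result` object with observed extrema, shuffled
#'   distributions, `excited` / `inhibited` flags and extremity percentiles.
#' @export
resampling_test <- function(trace, events, window = event_window(),
                            valid_periods = NULL, n_shuffles = 1000,
                            alpha = 0.05, seed = NULL, rate_hz = NULL) {
  if (n_shuffles < 100) stop("n_shuffles must be at least 100", call. = FALSE)
  tr <- as_trace(trace, rate_hz)
  wf <- window_frames(window, tr$rate_hz)
  n <- length(tr$values)
  onsets0 <- event_onset_frames(events, tr$rate_hz)
  es <- event_segments(tr$values, onsets0, wf$pre_f, wf$len_f)
  n_ev <- nrow(es$seg)
  if (n_ev == 0) stop("no event has a fully covered window", call. = FALSE)
  low_n <- n_ev < 3
  if (low_n) warning("fewer than 3 usable events; result flagged low-n", call. = FALSE)
  obs_mu <- colMeans(es$seg)
  obs_max <- max(obs_mu); obs_min <- min(obs_mu)

  # allowed pseudo-onset frames: window fully in the recording, onset time
  # inside the valid periods
  all0 <- (wf$pre_f):(n - (wf$len_f - wf$pre_f))  # 0-based onsets with coverage
  if (length(all0) == 0) stop("recording shorter than the analysis window", call. = FALSE)
  t_all <- all0 / tr$rate_hz
  allowed <- all0[in_valid_periods(t_all, valid_periods)]
  if (length(allowed) == 0) {
    stop("valid_periods leave no room for the analysis window", call. = FALSE)
  }

  with_seed(seed, {
    pseudo <- sample(allowed, n_ev * n_shuffles, replace = TRUE)
    start <- pseudo + 1L - wf$pre_f
    idx <- outer(start, 0:(wf$len_f - 1L), "+")
    vals <- matrix(tr$values[idx], nrow = length(start))
    grp <- rep(seq_len(n_shuffles), each = n_ev)
    mu <- rowsum(vals, grp, reorder = FALSE) / n_ev
    shuf_max <- do.call(pmax, as.data.frame(mu))
    shuf_min <- do.call(pmin, as.data.frame(mu))
    q_hi <- quantile(shuf_max, 1 - alpha, names = FALSE, type = 7)
    q_lo <- quantile(shuf_min, alpha, names = FALSE, type = 7)
    structure(list(
      observed_max = obs_max, observed_min = obs_min,
      shuffled_max = shuf_max, shuffled_min = shuf_min,
      excited = obs_max > q_hi, inhibited = obs_min < q_lo,
      extremity_excited = mean(shuf_max < obs_max),
      extremity_inhibited = mean(shuf_min > obs_min),
      q_hi = q_hi, q_lo = q_lo,
      alpha = alpha, n_shuffles = n_shuffles, n_events = n_ev,
      low_n = low_n
    ), class = "resampling_result")
  })
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Shuffle test (%d events, %d shuffles, alpha = %g/direction)\n",
              x$n_events, x$n_shuffles, x$alpha))
  cat(sprintf("  max %.4f vs q%.0f %.4f -> excited: %s\n",
              x$observed_max, 100 * (1 - x$alpha), x$q_hi, x$excited))
  cat(sprintf("  min %.4f vs q%.0f %.4f -> inhibited: %s\n",
              x$observed_min, 100 * x$alpha, x$q_lo, x$inhibited))
  invisible(x)
}

#' Per-event activation probability
#'
#' Fraction of events at which the cell responded: an event is "coded" when
#' the trace maximum inside its peri-event window strictly exceeds `k`
#' standard deviations of the baseline (frames outside every event window,
#' restricted to `valid_periods` when given). A constant trace yields
#' probability 0; a non-constant trace whose baseline has zero variance is an
#' error.
#'
#' @inheritParams resampling_test
#' @param k Threshold in baseline SDs (default 5).
#' @param baseline_frames Optional integer vector of 0-based frames to use as
#'   baseline instead of the default.
#' @return An `activation_result` list: `probability`, `n_events`, `n_coded`,
#'   `baseline_sd`, `k`, and `per_event` tibble (`onset_s`, `peak`, `coded`).
#' @export
activation_probability <- function(trace, events, window = event_window(),
                                   k = 5, baseline_frames = NULL,
                                   valid_periods = NULL, rate_hz = NULL) {
  tr <- as_trace(trace, rate_hz)
  wf <- window_frames(window, tr$rate_hz)
  n <- length(tr$values)
  onsets0 <- event_onset_frames(events, tr$rate_hz)
  start <- onsets0 + 1L - wf$pre_f
  keep <- start >= 1L & (start + wf$len_f - 1L) <= n
  if (!any(keep)) stop("no event has a fully covered window", call. = FALSE)
  if (is.null(baseline_frames)) {
    in_window <- rep(FALSE, n)
    for (s in start[keep]) in_window[s:(s + wf$len_f - 1L)] <- TRUE
    base_idx <- which(!in_window)
    if (!is.null(valid_periods)) {
      base_idx <- base_idx[in_valid_periods((base_idx - 1L) / tr$rate_hz, valid_periods)]
    }
  } else {
    base_idx <- baseline_frames + 1L
    base_idx <- base_idx[base_idx >= 1L & base_idx <= n]
  }
  if (length(base_idx) < 2) stop("baseline is empty", call. = FALSE)
  base_sd <- sd(tr$values[base_idx])
  if (!is.finite(base_sd)) stop("baseline SD is undefined", call. = FALSE)
  if (base_sd == 0 && sd(tr$values) > 0) {
    stop("baseline SD is zero for a non-constant trace", call. = FALSE)
  }
  es <- event_segments(tr$values, onsets0, wf$pre_f, wf$len_f)
  peaks <- apply(es$seg, 1, max)
  coded <- peaks > k * base_sd
  onset_kept <- if (is.data.frame(events)) events$onset_s[keep] else as.numeric(events)[keep]
  structure(list(
    probability = mean(coded), n_events = length(coded), n_coded = sum(coded),
    baseline_sd = base_sd, k = k,
    per_event = tibble(onset_s = onset_kept, peak = peaks, coded = coded)
  ), class = "activation_result")
}

#' @export
print.activation_result <- function(x, ...) {
  cat(sprintf("Activation probability: %d / %d events coded (p = %.3f, k = %g SD)\n",
              x$n_coded, x$n_events, x$probability, x$k))
  invisible(x)
}

#' Correlate per-event response amplitude with movement kinematics
#'
#' Pearson correlation between per-event response peaks and one or more
#' kinematic covariates (e.g. pre-stop mean speed, peak deceleration, run
#' duration, post-start speed), with a permutation p-value obtained by
#' shuffling the peak-kinematics pairing.
#'
#' @param data Tibble with one row per event.
#' @param peak_col Name of the response-amplitude column (default `"peak"`).
#' @param kin_cols Character vector of kinematic columns; default: every
#'   other numeric column.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for the permutations.
#' @return Tibble with one row per kinematic variable: `variable`, `n`, `r`,
#'   `p_perm`, `flag` (`"ok"`, `"zero_variance"`).
#' @export
kinematic_correlation <- function(data, peak_col = "peak", kin_cols = NULL,
                                  n_perm = 1000, seed = NULL) {
  stopifnot(is.data.frame(data), peak_col %in% names(data))
  if (is.null(kin_cols)) {
    kin_cols <- setdiff(names(data)[vapply(data, is.numeric, TRUE)], peak_col)
  }
  if (!length(kin_cols)) stop("no kinematic columns", call. = FALSE)
  with_seed(seed, {
    purrr::map(kin_cols, function(v) {
      ok <- complete.cases(data[[peak_col]], data[[v]])
      x <- data[[peak_col]][ok]; y <- data[[v]][ok]
      if (length(x) < 5) stop("need at least 5 events with defined kinematics for ", v, call. = FALSE)
      if (sd(y) == 0 || sd(x) == 0) {
        return(tibble(variable = v, n = length(x), r = NA_real_,
                      p_perm = NA_real_, flag = "zero_variance"))
      }
      r <- cor(x, y)
      rp <- vapply(seq_len(n_perm), function(i) cor(sample(x), y), numeric(1))
      p <- (1 + sum(abs(rp) >= abs(r) - 1e-12)) / (n_perm + 1)
      tibble(variable = v, n = length(x), r = r, p_perm = p, flag = "ok")
    }) %>% list_rbind()
  })
}
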