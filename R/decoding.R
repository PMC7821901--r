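# Population decoding of the locomotor state: frame-wise feature matrix,
# jack-knifed linear SVM with contiguous train/test chunks, ROC/AUC, and the
# unpredicted-stop diagnostic.

#' Build the frame-wise population matrix
#'
#' Assembles per-frame population activity vectors and binary labels
#' (walking = forward = 1, stationary = 0). Backward frames are excluded
#' (label undefined); frames outside `valid_periods` are masked out.
#'
#' @param traces Wide trace tibble (`time_s` + one column per cell), e.g.
#'   smoothed dF/F.
#' @param states Per-frame state labels on the same clock (character vector
#'   of `"forward"`/`"stationary"`/`"backward"`), or a speed-trace tibble
#'   whose clock matches the traces. Use [align_states()] first when the
#'   behaviour video runs at a different rate.
#' @param valid_periods Optional tibble (`start_s`, `end_s`).
#' @return A `population_matrix` list: `x` (frames x cells), `label` (0/1/NA),
#'   `valid` (logical), `time_s`, `cells`, `n_backward`, `untrainable`.
#' @export
build_population_matrix <- function(traces, states, valid_periods = NULL) {
  tm <- trace_matrix(traces)
  if (is.data.frame(states)) {
    if (nrow(states) != nrow(traces) ||
        max(abs(states$time_s - traces$time_s)) > 0.5 / infer_rate(traces$time_s)) {
      stop("state clock does not match the trace clock; use align_states()", call. = FALSE)
    }
    states <- states$state
  }
  if (length(states) != nrow(traces)) {
    stop("states length does not match the number of trace frames", call. = FALSE)
  }
  label <- dplyr::case_match(states, "forward" ~ 1, "stationary" ~ 0,
                             "backward" ~ NA_real_)
  valid <- !is.na(label) & in_valid_periods(tm$time_s, valid_periods)
  structure(list(
    x = tm$x, label = label, valid = valid, time_s = tm$time_s,
    cells = tm$cells, n_backward = sum(states == "backward"),
    untrainable = length(unique(label[valid])) < 2
  ), class = "population_matrix")
}

#' ROC curve and AUC from decision values
#'
#' Sweeps all unique thresholds of the decision values and returns the ROC
#' points together with the trapezoid-rule AUC, which equals the normalised
#' Mann-Whitney U statistic (ties counted 1/2).
#'
#' @param scores Numeric decision values (higher = more "positive").
#' @param labels Binary labels (0/1, logical, or factor with two levels).
#' @return A list: `roc` (tibble `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(as.logical(as.numeric(labels)))
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  rk <- rank(scores)   # midranks handle ties as 1/2
  auc <- (sum(rk[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(y[ord]); fp <- cumsum(1 - y[ord])
  uniq <- c(diff(scores[ord]) != 0, TRUE)   # last index of each unique score
  roc <- tibble(
    threshold = c(Inf, scores[ord][uniq]),
    fpr = c(0, fp[uniq] / n0),
    tpr = c(0, tp[uniq] / n1)
  )
  list(roc = roc, auc = auc)
}

#' Jack-knifed linear-SVM decoding of the locomotor state
#'
#' Fits a linear maximum-margin classifier (hinge loss, L2 regularisation,
#' class-balanced weights; `e1071::svm`, cost fixed, no tuning) on random
#' contiguous 80% chunks of the valid frames, evaluates decision values on
#' the held-out 20%, and averages the ROC AUC over `n_splits` splits.
#' Contiguous chunks limit temporal leakage from calcium autocorrelation.
#' A final model fitted on all valid frames provides the frame-wise predicted
#' state used by [unpredicted_stops()].
#'
#' @param pm A [build_population_matrix()] result.
#' @param n_splits Number of jack-knife repetitions (default 5).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Seed for the chunk placement.
#' @param cost SVM cost parameter (default 1).
#' @return A `decoding_report` list: `auc` (per split), `mean_auc`, `roc`
#'   (list of per-split tibbles), `predicted` (tibble `time_s`, `label`,
#'   `predicted`), `n_cells`, `n_frames`, `n_resampled`.
#' @export
jackknife_train_eval <- function(pm, n_splits = 5, train_frac = 0.8,
                                 seed = NULL, cost = 1) {
  stopifnot(inherits(pm, "population_matrix"))
  if (pm$untrainable) stop("only one class present; decoding is undefined", call. = FALSE)
  v <- which(pm$valid)
  n_test <- max(1L, round((1 - train_frac) * length(v)))
  if (n_test >= length(v)) stop("not enough valid frames", call. = FALSE)

  fit_svm <- function(idx) {
    y <- factor(pm$label[idx], levels = c("0", "1"))
    w <- 1 / table(y)
    w <- w / sum(w) * 2
    e1071::svm(pm$x[idx, , drop = FALSE], y, kernel = "linear", cost = cost,
               class.weights = setNames(as.numeric(w), names(w)), scale = TRUE)
  }
  decision_for_1 <- function(fit, idx) {
    pr <- stats::predict(fit, pm$x[idx, , drop = FALSE], decision.values = TRUE)
    dv <- attr(pr, "decision.values")[, 1]
    pos_first <- strsplit(colnames(attr(pr, "decision.values"))[1], "/")[[1]][1]
    if (pos_first == "1") dv else -dv
  }

  with_seed(seed, {
    aucs <- numeric(n_splits)
    rocs <- vector("list", n_splits)
    n_resampled <- 0L
    for (s in seq_len(n_splits)) {
      for (try in 1:20) {
        a <- sample(length(v) - n_test + 1L, 1)
        test <- v[a:(a + n_test - 1L)]
        train <- setdiff(v, test)
        ok <- length(unique(pm$label[train])) == 2 && length(unique(pm$label[test])) == 2
        if (ok) break
        n_resampled <- n_resampled + 1L
        if (try == 20) stop("could not draw a split with both classes", call. = FALSE)
      }
      fit <- fit_svm(train)
      ra <- roc_auc(decision_for_1(fit, test), pm$label[test])
      aucs[s] <- ra$auc
      rocs[[s]] <- ra$roc
    }
    full <- fit_svm(v)
    pred <- rep(NA_character_, length(pm$label))
    pred[v] <- ifelse(as.character(stats::predict(full, pm$x[v, , drop = FALSE])) == "1",
                      "walking", "stationary")
    structure(list(
      auc = aucs, mean_auc = mean(aucs), roc = rocs,
      predicted = tibble(time_s = pm$time_s, label = pm$label, predicted = pred),
      n_cells = length(pm$cells), n_frames = length(v),
      n_splits = n_splits, n_resampled = n_resampled
    ), class = "decoding_report")
  })
}

#' @export
print.decoding_report <- function(x, ...) {
  cat(sprintf("Decoding report: %d cells, %d valid frames, %d splits\n",
              x$n_cells, x$n_frames, x$n_splits))
  cat("  AUC per split:", paste(sprintf("%.3f", x$auc), collapse = ", "), "\n")
  cat(sprintf("  mean AUC: %.3f\n", x$mean_auc))
  invisible(x)
}

#' Stops missed by the population decoder
#'
#' A stop event counts as predicted when at least one frame of its post-onset
#' window (`[onset, onset + post_s)`) is decoded as stationary; otherwise it
#' is returned as unpredicted.
#'
#' @param report A [jackknife_train_eval()] result.
#' @param events Event-list tibble of stops.
#' @param post_s Post-onset window length (s), default 1.25.
#' @return The subset of `events` that was not predicted.
#' @export
unpredicted_stops <- function(report, events, post_s = 1.25) {
  stopifnot(inherits(report, "decoding_report"))
  pr <- report$predicted
  miss <- vapply(seq_len(nrow(events)), function(i) {
    idx <- pr$time_s >= events$onset_s[i] & pr$time_s < events$onset_s[i] + post_s
    !any(pr$predicted[idx] == "stationary", na.rm = TRUE)
  }, logical(1))
  events[miss, , drop = FALSE]
}
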