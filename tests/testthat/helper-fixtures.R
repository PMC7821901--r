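# Builders shared across test files. Everything is generated in code; no
# stored binary fixtures.

# Speed trace straight from a per-frame speed vector (states classified with
# the default thresholds).
speed_trace_from <- function(speed, rate_hz = 20) {
  n <- length(speed)
  out <- tibble::tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / rate_hz,
    speed_cms = speed,
    state = classify_state(speed)
  )
  attr(out, "rate_hz") <- rate_hz
  out
}

# Landmark track for a straight walk along +x with per-frame positions.
straight_track <- function(pos_x, rate_hz = 20, ear_sep = 1.5, spine_back = 2) {
  n <- length(pos_x)
  tibble::tibble(
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / rate_hz,
    left_ear_x = pos_x, left_ear_y = ear_sep / 2,
    right_ear_x = pos_x, right_ear_y = -ear_sep / 2,
    spine_x = pos_x - spine_back, spine_y = 0
  )
}

# Event list at given onset times (s).
events_at <- function(onset_s, event = "stop", rate_hz = 20) {
  tibble::tibble(
    event = event,
    onset_s = onset_s,
    onset_frame = as.integer(floor(onset_s * rate_hz + 0.5)),
    offset_s = NA_real_,
    provenance = "detected"
  )
}

# dF/F trace with unit-peak transients planted at given frames (0-based).
planted_trace <- function(n_frames, onset_frames, amp = 1, noise_sd = 0,
                          seed = NULL, config = sim_config(noise_sd = noise_sd)) {
  events_to_calcium(onset_frames, amp, n_frames, config,
                    noise_sd = noise_sd, seed = seed)$dff
}

# Independent Freeman-Halton oracle for two-row tables. Uses the
# multivariate-hypergeometric form prod(choose(c_j, a_j)) / choose(N, r_1)
# over a vectorised grid of first rows -- a different table generation and a
# different probability formula than the package's factorial-form DFS.
fisher_oracle_2xc <- function(x) {
  x <- as.matrix(x)
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2) return(1)
  stopifnot(nrow(x) == 2)
  cs <- colSums(x); r1 <- rowSums(x)[1]; N <- sum(x)
  grid <- as.matrix(expand.grid(lapply(cs, function(cj) 0:cj)))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  p <- apply(grid, 1, function(a) prod(choose(cs, a))) / choose(N, r1)
  p_obs <- prod(choose(cs, x[1, ])) / choose(N, r1)
  min(1, sum(p[p <= p_obs * (1 + 1e-9)]))
}

# All k-tuples of nonnegative integers with sum <= cap (one row per tuple).
compositions_leq <- function(k, cap) {
  if (k == 1) return(matrix(0:cap, ncol = 1))
  do.call(rbind, lapply(0:cap, function(v) {
    cbind(v, compositions_leq(k - 1, cap - v))
  }))
}
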