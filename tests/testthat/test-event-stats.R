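# Event-triggered averages, shuffle test, activation probability and
# kinematic correlations.

test_that("event-triggered average has the right window geometry and moments", {
  rate <- 20
  x <- rep(0.7, 600)
  ev <- events_at(c(5, 10, 15))
  ea <- event_triggered_average(x, ev, rate_hz = rate)
  expect_length(ea$mean, 30)             # 1.5 s at 20 Hz
  expect_equal(ea$time_rel_s[1], -0.25)  # window starts 0.25 s before onset
  expect_equal(ea$mean, rep(0.7, 30))
  expect_equal(ea$sem, rep(0, 30))
  expect_equal(ea$peak, 0.7)
  expect_equal(ea$trough, 0.7)

  # planted identical transient at every event, spaced far beyond the
  # kernel support so windows are overlap-free
  cfg <- sim_config(noise_sd = 0)
  on <- c(100L, 500L, 900L, 1300L)
  tr <- planted_trace(1500, on, amp = 1)
  ea2 <- event_triggered_average(tr, events_at(on / rate), rate_hz = rate)
  seg <- calcium_kernel(ea2$time_rel_s, cfg$kernel_rise_s, cfg$kernel_decay_s)
  expect_equal(ea2$mean, seg, tolerance = 1e-9)
  expect_equal(ea2$peak, max(seg), tolerance = 1e-9)
  expect_gte(ea2$dt_peak_s, 0)           # transient peaks after the onset
  expect_lte(ea2$dt_peak_s, 0.5)

  # single event: mean equals the segment, SEM flagged undefined
  ea3 <- event_triggered_average(tr, events_at(on[1] / rate), rate_hz = rate)
  expect_false(ea3$sem_defined)
  expect_true(all(is.na(ea3$sem)))

  # events without full coverage are dropped and counted
  ea4 <- event_triggered_average(tr, events_at(c(0.05, 10)), rate_hz = rate)
  expect_equal(ea4$n_events, 1)
  expect_equal(ea4$n_dropped, 1)
  expect_error(event_triggered_average(tr, events_at(0.05), rate_hz = rate),
               "fully covered")
})

test_that("event average scales linearly with the trace", {
  tr <- planted_trace(600, c(100L, 300L), amp = 1, noise_sd = 0.05, seed = 5)
  ev <- events_at(c(5, 15))
  a <- event_triggered_average(tr, ev, rate_hz = 20)
  b <- event_triggered_average(3 * tr, ev, rate_hz = 20)
  expect_equal(b$peak, 3 * a$peak, tolerance = 1e-12)
  expect_equal(b$mean, 3 * a$mean, tolerance = 1e-12)
})

test_that("a constant trace is never called significant (ties lose)", {
  x <- rep(0.2, 1200)
  res <- resampling_test(x, events_at(c(10, 20, 30, 40)), rate_hz = 20,
                         n_shuffles = 200, seed = 1)
  expect_false(res$excited)
  expect_false(res$inhibited)
})

test_that("a planted responsive cell is flagged excited, reproducibly", {
  set.seed(99)
  on <- sort(sample(100:1800, 40))
  hit <- runif(40) < 0.8
  tr <- planted_trace(2000, on[hit], amp = 0.3, noise_sd = 0.1, seed = 7)
  ev <- events_at(on / 20)
  r1 <- resampling_test(tr, ev, rate_hz = 20, seed = 11)
  expect_true(r1$excited)
  expect_false(r1$inhibited)
  r2 <- resampling_test(tr, ev, rate_hz = 20, seed = 11)
  expect_identical(r1$shuffled_max, r2$shuffled_max)
  r3 <- resampling_test(tr, ev, rate_hz = 20, seed = 12)
  expect_false(identical(r1$shuffled_max, r3$shuffled_max))
})

test_that("shuffles respect valid periods and fail when no room is left", {
  tr <- planted_trace(1200, c(200L, 400L, 600L), amp = 1, noise_sd = 0.05, seed = 2)
  ev <- events_at(c(10, 20, 30))
  vp <- tibble::tibble(start_s = 5, end_s = 40)
  r <- resampling_test(tr, ev, valid_periods = vp, rate_hz = 20, seed = 1)
  expect_s3_class(r, "resampling_result")
  expect_error(
    resampling_test(tr, ev, valid_periods = tibble::tibble(start_s = 59.9, end_s = 60),
                    rate_hz = 20, seed = 1),
    "valid_periods")
  expect_warning(
    resampling_test(tr, events_at(c(10, 20)), rate_hz = 20, seed = 1, n_shuffles = 100),
    "low-n")
})

test_that("activation probability recovers the planted coded fraction", {
  rate <- 20; noise <- 0.02
  on <- seq(100, 1900, by = 200)          # 10 events
  coded_idx <- c(1, 3, 4, 6, 8, 10)       # 6 of 10 respond
  tr <- planted_trace(2100, on[coded_idx], amp = 10 * noise * 5, # 10x threshold margin
                      noise_sd = noise, seed = 3)
  ap <- activation_probability(tr, events_at(on / rate), rate_hz = rate)
  expect_equal(ap$probability, 0.6)
  expect_equal(ap$n_coded, 6)

  # all events coded -> 1; flat trace -> 0
  tr2 <- planted_trace(2100, on, amp = 1, noise_sd = noise, seed = 4)
  expect_equal(activation_probability(tr2, events_at(on / rate), rate_hz = rate)$probability, 1)
  expect_equal(activation_probability(rep(0, 2100), events_at(on / rate),
                                      rate_hz = rate)$probability, 0)
  # non-constant trace with a zero-variance baseline is an error
  tr3 <- rep(0, 2100); tr3[on + 1] <- 1
  expect_error(
    activation_probability(tr3, events_at(on / rate), rate_hz = rate,
                           baseline_frames = seq(0L, 50L)),
    "zero")
})

test_that("activation probability is monotone in transient amplitude", {
  rate <- 20; noise <- 0.05
  on <- seq(100, 1900, by = 100)
  probs <- sapply(c(0.05, 0.15, 0.3, 0.6, 1.2), function(a) {
    tr <- planted_trace(2100, on, amp = a, noise_sd = noise, seed = 6)
    activation_probability(tr, events_at(on / rate), rate_hz = rate)$probability
  })
  expect_true(all(diff(probs) >= 0))
})

test_that("kinematic correlations recover proportionality and antisymmetry", {
  set.seed(1)
  speed <- runif(30, 5, 25)
  d <- tibble::tibble(peak = 0.02 * speed, pre_speed = speed)
  out <- kinematic_correlation(d, n_perm = 200, seed = 1)
  expect_equal(out$r, 1, tolerance = 1e-12)
  d2 <- d; d2$pre_speed <- -d2$pre_speed
  out2 <- kinematic_correlation(d2, n_perm = 200, seed = 1)
  expect_equal(out2$r, -out$r, tolerance = 1e-12)
  # zero-variance covariate is flagged, not an error
  d3 <- tibble::tibble(peak = runif(10), flatline = rep(1, 10))
  out3 <- kinematic_correlation(d3, n_perm = 100, seed = 1)
  expect_equal(out3$flag, "zero_variance")
  expect_true(is.na(out3$r))
})

test_that("independent kinematics rarely beat the permutation bound", {
  ok <- 0
  for (s in 1:10) {
    set.seed(1000 + s)
    d <- tibble::tibble(peak = rnorm(40), pre_speed = runif(40, 5, 25))
    out <- kinematic_correlation(d, n_perm = 400, seed = s)
    if (out$p_perm > 0.05) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("pre-stop kinematics summarise the preceding run", {
  cfg <- sim_config(duration_s = 60, seed = 14)
  bs <- simulate_behavior(cfg)
  stops <- detect_stops(bs$speed)
  kin <- stop_kinematics(bs$speed, stops)
  expect_equal(nrow(kin), nrow(stops))
  expect_true(all(kin$pre_speed_cms > 0))
  expect_true(all(kin$peak_decel_cms2 > 0))
  expect_true(all(kin$run_duration_s >= 0.25 - 1e-9, na.rm = TRUE))
})
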