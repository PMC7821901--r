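# Oriented speed, state classification and event detection.

test_that("oriented speed is zero for a stationary animal", {
  tr <- straight_track(rep(5, 40))
  sp <- oriented_speed(tr)
  expect_equal(sp$speed_cms, rep(0, 40))
  expect_true(all(sp$state == "stationary"))
})

test_that("pure translation along the body axis recovers the speed", {
  rate <- 20
  tr <- straight_track(4 * (0:39) / rate, rate_hz = rate)
  sp <- oriented_speed(tr)
  expect_equal(sp$speed_cms[-1], rep(4, 39), tolerance = 1e-12)
  expect_equal(sp$speed_cms[1], sp$speed_cms[2])  # first frame copies second
  expect_true(all(sp$state == "forward"))
})

test_that("circular walk at constant tangential speed recovers the speed within 2%", {
  # heading tangent to a circle of radius R; the ear midpoint moves along the
  # circle at v cm/s. Oracle: the chord/arc analysis of the parametric path.
  R <- 10; v <- 8; rate <- 50
  t <- (0:499) / rate
  th <- v * t / R
  mid_x <- R * cos(th); mid_y <- R * sin(th)
  hx <- -sin(th); hy <- cos(th)          # unit tangent
  ear_off <- 0.75
  track <- tibble::tibble(
    time_s = t,
    left_ear_x = mid_x - ear_off * hy, left_ear_y = mid_y + ear_off * hx,
    right_ear_x = mid_x + ear_off * hy, right_ear_y = mid_y - ear_off * hx,
    spine_x = mid_x - 2 * hx, spine_y = mid_y - 2 * hy
  )
  sp <- oriented_speed(track)
  interior <- sp$speed_cms[-1]
  expect_true(all(abs(interior - v) / v < 0.02))
})

test_that("degenerate orientation frames reuse the previous orientation", {
  tr <- straight_track(seq(0, 4, length.out = 41))
  # collapse the landmarks onto one point mid-way
  tr[20, c("left_ear_x", "right_ear_x", "spine_x")] <- 1.9
  tr[20, c("left_ear_y", "right_ear_y", "spine_y")] <- 0
  sp <- oriented_speed(tr)
  expect_true(all(is.finite(sp$speed_cms)))
})

test_that("state thresholds are strict and signed", {
  expect_equal(classify_state(c(5, 0, -5, 3, -3)),
               c("forward", "stationary", "backward", "stationary", "stationary"))
})

test_that("stop detection applies the immobility, run-duration and run-speed rules", {
  rate <- 20
  # 1 s at 10 cm/s then 1 s immobile -> one stop at the transition frame
  sp <- speed_trace_from(c(rep(10, 20), rep(0, 20)), rate)
  st <- detect_stops(sp)
  expect_equal(nrow(st), 1)
  expect_equal(st$onset_frame, 20L)
  expect_equal(st$onset_s, 1.0)

  # run of 0.2 s (< 0.25 s) -> rejected
  sp2 <- speed_trace_from(c(rep(0, 20), rep(10, 4), rep(0, 20)), rate)
  expect_equal(nrow(detect_stops(sp2)), 0)

  # run average speed 4 cm/s (< 5) -> rejected
  sp3 <- speed_trace_from(c(rep(4, 20), rep(0, 20)), rate)
  expect_equal(nrow(detect_stops(sp3)), 0)

  # immobility shorter than 200 ms -> rejected
  sp4 <- speed_trace_from(c(rep(10, 20), rep(0, 3), rep(10, 20)), rate)
  expect_equal(nrow(detect_stops(sp4)), 0)

  expect_equal(nrow(detect_stops(speed_trace_from(numeric(0)))), 0)
})

test_that("long-stop detection drops the speed-average rule and needs 3 s immobility", {
  rate <- 20
  mk <- function(run_s, imm_s, v = 4) {
    speed_trace_from(c(rep(0, 10), rep(v, round(run_s * rate)), rep(0, round(imm_s * rate))), rate)
  }
  expect_equal(nrow(detect_long_stops(mk(0.15, 2.9))), 0)   # immobility < 3 s
  ls <- detect_long_stops(mk(0.15, 3.5))
  expect_equal(nrow(ls), 1)                                  # slow 150 ms run is enough
  expect_equal(ls$event, "long_stop")
  # nesting: a long stop whose run also satisfies the stop rules is a stop too
  sp <- mk(1, 3.5, v = 10)
  expect_equal(detect_long_stops(sp)$onset_frame, detect_stops(sp)$onset_frame)
})

test_that("start detection applies stationary-duration and pre-speed rules", {
  rate <- 20
  sp <- speed_trace_from(c(rep(0, 20), rep(10, 20)), rate)
  st <- detect_starts(sp)
  expect_equal(nrow(st), 1)
  expect_equal(st$onset_frame, 20L)

  # jittery 'stationary' period with mean |speed| 2.5 cm/s -> rejected
  sp2 <- speed_trace_from(c(rep(2.5, 20), rep(10, 20)), rate)
  expect_equal(nrow(detect_starts(sp2)), 0)

  expect_equal(nrow(detect_starts(speed_trace_from(rep(0, 100)))), 0)
})

test_that("stationary padding at the end does not change detected stops", {
  cfg <- sim_config(duration_s = 60, seed = 11)
  sp <- simulate_behavior(cfg)$speed
  st1 <- detect_stops(sp)
  pad <- speed_trace_from(c(sp$speed_cms, rep(0, 100)), attr(sp, "rate_hz"))
  st2 <- detect_stops(pad)
  expect_equal(st1$onset_frame, st2$onset_frame)
})

test_that("raising the run-speed threshold never adds stops", {
  cfg <- sim_config(duration_s = 120, seed = 5,
                    run_speed_cms = 8)
  sp <- simulate_behavior(cfg)$speed
  counts <- sapply(c(0, 2, 5, 7.9, 8.5), function(th) {
    nrow(detect_stops(sp, min_avg_run_speed = th))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("valid_periods restrict events to the requested windows", {
  cfg <- sim_config(duration_s = 120, seed = 7)
  sp <- simulate_behavior(cfg)$speed
  vp <- tibble::tibble(start_s = 30, end_s = 60)
  for (det in list(detect_stops, detect_long_stops, detect_starts)) {
    ev <- det(sp, valid_periods = vp)
    expect_true(all(ev$onset_s >= 30 & ev$onset_s < 60))
  }
})

test_that("annotations are read, validated and bounded", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("type,onset_s,offset_s",
               "grooming,10.5,14",
               "grooming,33,40.2",
               "grooming,51.25,58"), f)
  ev <- read_annotations(f, recording_end_s = 60, rate_hz = 20)
  expect_equal(nrow(ev), 3)
  expect_true(all(ev$event == "grooming"))
  expect_true(all(ev$provenance == "annotated"))
  expect_equal(ev$onset_frame, c(210L, 660L, 1025L))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines("type,onset_s", f2)
  expect_equal(nrow(read_annotations(f2, recording_end_s = 60)), 0)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("type,onset_s", "stop,30", "stop,75"), f3)
  expect_error(read_annotations(f3, recording_end_s = 60), "row 2")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("type,onset_s", "wiggle,3"), f4)
  expect_error(read_annotations(f4, recording_end_s = 60), "unknown event type")
})

test_that("state alignment maps a 50 Hz behaviour clock onto 20 Hz frames", {
  cfg <- sim_config(duration_s = 30, behavior_rate_hz = 50, seed = 2)
  bs <- simulate_behavior(cfg)
  t20 <- seq(0, 30, by = 0.05)
  states <- align_states(bs$speed, t20)
  expect_length(states, length(t20))
  # at shared timestamps the mapping is exact
  shared <- which(t20 %in% bs$speed$time_s)
  expect_equal(states[shared],
               bs$speed$state[match(t20[shared], bs$speed$time_s)])
})
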