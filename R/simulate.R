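# Synthetic behaviour + calcium generator. Produces coupled landmark tracks,
# oriented-speed traces, ground-truth event lists and GCaMP6s-like dF/F
# traces from planted cell classes, so every downstream stage has a
# parameter-recovery test surface.

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic generator. Bout and
#' immobility durations are drawn from an exponential distribution with the
#' given mean, rejected outside `[min, max]`; `min == max` forces a fixed
#' duration. The calcium transient kernel is a difference of exponentials
#' with the given rise and decay constants (defaults 75 ms and 0.5 s,
#' GCaMP6s-like), normalised to unit peak.
#'
#' @param duration_s Recording duration (s).
#' @param behavior_rate_hz Behaviour video rate; 20 or 50 Hz.
#' @param calcium_rate_hz Calcium imaging rate; fixed at 20 Hz.
#' @param bout_duration_s List `mean`/`min`/`max` (s) of locomotion bouts.
#' @param immobility_duration_s List `mean`/`min`/`max` (s) of immobility.
#' @param grooming_prob Probability that an immobility period contains a
#'   grooming epoch (grooming only ever occurs while stationary).
#' @param p_bout Probability that each scheduled locomotion bout is actually
#'   expressed; 0 yields an all-stationary recording.
#' @param run_speed_cms Cruising speed during bouts (cm/s).
#' @param noise_sd White-noise standard deviation added to dF/F traces.
#' @param kernel_rise_s,kernel_decay_s Transient rise/decay constants (s);
#'   decay must exceed rise.
#' @param ramp_s Duration of the linear speed ramps at bout edges (s). Ramps
#'   give the deceleration before a stop a defined kinematic value.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(duration_s = 600,
                       behavior_rate_hz = 20,
                       calcium_rate_hz = 20,
                       bout_duration_s = list(mean = 5, min = 1, max = 20),
                       immobility_duration_s = list(mean = 2, min = 0.5, max = 10),
                       grooming_prob = 0.15,
                       p_bout = 1,
                       run_speed_cms = 15,
                       noise_sd = 0.05,
                       kernel_rise_s = 0.075,
                       kernel_decay_s = 0.5,
                       ramp_s = 0.1,
                       seed = 1L) {
  stopifnot(duration_s > 0, ramp_s > 0, run_speed_cms > 0, noise_sd >= 0)
  if (!behavior_rate_hz %in% c(20, 50)) stop("behavior_rate_hz must be 20 or 50", call. = FALSE)
  if (calcium_rate_hz != 20) stop("calcium_rate_hz must be 20", call. = FALSE)
  for (d in list(bout_duration_s, immobility_duration_s)) {
    stopifnot(all(c("mean", "min", "max") %in% names(d)),
              d$min > 0, d$max >= d$min, d$mean > 0)
  }
  if (grooming_prob < 0 || grooming_prob > 1) stop("grooming_prob must be in [0, 1]", call. = FALSE)
  if (p_bout < 0 || p_bout > 1) stop("p_bout must be in [0, 1]", call. = FALSE)
  if (!(kernel_decay_s > kernel_rise_s && kernel_rise_s > 0)) {
    stop("need kernel_decay_s > kernel_rise_s > 0", call. = FALSE)
  }
  structure(list(
    duration_s = duration_s, behavior_rate_hz = behavior_rate_hz,
    calcium_rate_hz = calcium_rate_hz, bout_duration_s = bout_duration_s,
    immobility_duration_s = immobility_duration_s, grooming_prob = grooming_prob,
    p_bout = p_bout, run_speed_cms = run_speed_cms, noise_sd = noise_sd,
    kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
    ramp_s = ramp_s, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Ground-truth cell definition
#'
#' Describes a planted cell for the synthetic generator. Classes mirror the
#' functional types seen in brainstem imaging during locomotion: cells excited
#' at stops (with event-wise reliability), tonically active cells inhibited at
#' stops, start-excited cells, grooming-excited cells, and cells uncorrelated
#' with behaviour.
#'
#' @param cell_id Cell identifier.
#' @param cell_class One of `"stop_excited"`, `"stop_inhibited"`,
#'   `"start_excited"`, `"grooming_excited"`, `"uncorrelated"`.
#' @param reliability_p Probability that a preferred event evokes a response.
#' @param response_amp Rate bump amplitude (a.u./s) added at responded events
#'   (or, for inhibited cells, the tonic baseline that gets suppressed is
#'   fixed; see [simulate_cell_rate()]).
#' @param sustained If `TRUE` the response persists through the following
#'   behavioural state rather than being a brief bump.
#' @param location Implant position label, `"medial"` or `"lateral"`.
#' @return A one-row tibble.
#' @export
ground_truth_cell <- function(cell_id, cell_class, reliability_p = 0.8,
                              response_amp = 10, sustained = FALSE,
                              location = "lateral") {
  classes <- c("stop_excited", "stop_inhibited", "start_excited",
               "grooming_excited", "uncorrelated")
  if (!cell_class %in% classes) stop("unknown cell_class: ", cell_class, call. = FALSE)
  if (reliability_p < 0 || reliability_p > 1) stop("reliability_p must be in [0, 1]", call. = FALSE)
  if (response_amp < 0) stop("response_amp must be >= 0", call. = FALSE)
  if (!location %in% c("medial", "lateral")) stop("location must be medial or lateral", call. = FALSE)
  tibble(cell_id = as.character(cell_id), cell_class = cell_class,
         reliability_p = reliability_p, response_amp = response_amp,
         sustained = sustained, location = location)
}

#' Default synthetic cohort
#'
#' Builds a cohort tibble with planted class fractions (default: half
#' stop-excited, a quarter stop-inhibited, a quarter uncorrelated, mirroring
#' the heterogeneity reported for brainstem V2a populations), alternating
#' medial/lateral locations.
#'
#' @param n Number of cells.
#' @param fractions Named numeric vector of class fractions summing to 1.
#' @param reliability_p,response_amp,sustained Passed to every cell.
#' @return Tibble of ground-truth cells.
#' @export
default_cohort <- function(n = 20,
                           fractions = c(stop_excited = 0.5, stop_inhibited = 0.25,
                                         uncorrelated = 0.25),
                           reliability_p = 0.8, response_amp = 10, sustained = FALSE) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  counts <- round(fractions * n)
  counts[1] <- n - sum(counts[-1])
  classes <- rep(names(counts), counts)
  purrr::imap(classes, function(cl, i) {
    ground_truth_cell(sprintf("cell_%02d", i), cl, reliability_p = reliability_p,
                      response_amp = response_amp, sustained = sustained,
                      location = if (i %% 2 == 0) "medial" else "lateral")
  }) %>% list_rbind()
}

# Draw one duration from a truncated exponential (rejection sampling).
draw_duration <- function(spec) {
  if (spec$min == spec$max) return(spec$min)
  for (i in 1:1000) {
    x <- rexp(1, rate = 1 / spec$mean)
    if (x >= spec$min && x <= spec$max) return(x)
  }
  # pathological truncation; fall back to the interval midpoint
  (spec$min + spec$max) / 2
}

#' Simulate behaviour: schedule, speed trace and landmark track
#'
#' Generates an alternating immobility/locomotion schedule, synthesises the
#' corresponding oriented-speed profile (cruising at `run_speed_cms` with
#' linear ramps of `ramp_s` at bout edges, zero while stationary), lays a
#' minimal landmark geometry over it (ear midpoint on the trajectory, spine
#' 2 cm behind along the heading, ears 1.5 cm apart), and derives the emitted
#' speed trace by passing that track through [oriented_speed()], so trace and
#' landmarks are consistent by construction.
#'
#' Ground-truth stop/start onsets are expressed on the emitted frame clock:
#' a stop is the first frame classified stationary after a forward run, a
#' start the first forward frame after a stationary period, and a long stop
#' a stop whose stationary run spans at least 3 s of frames. Scheduled bout
#' and immobility durations always satisfy the detection criteria, so the
#' ground truth lists every qualifying event. Grooming epochs only occur
#' inside immobility periods (grooming and locomotion are mutually
#' exclusive); their onsets come from the schedule.
#'
#' @param config A [sim_config()].
#' @return A list of class `behavior_sim`: `schedule` (tibble `state`,
#'   `start_s`, `end_s`), `landmarks`, `speed` (an [oriented_speed()] trace),
#'   `events` (ground-truth event list, provenance `"ground_truth"`), and
#'   `config`.
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    dur <- config$duration_s
    # --- interval plan: immobility first, then alternating bouts ---
    plan_state <- character(0)
    plan_len <- numeric(0)
    t <- 0
    repeat {
      imm <- draw_duration(config$immobility_duration_s)
      if (t + imm > dur) break
      plan_state <- c(plan_state, "stationary"); plan_len <- c(plan_len, imm)
      t <- t + imm
      bout <- draw_duration(config$bout_duration_s)
      if (t + bout > dur) break
      if (runif(1) <= config$p_bout && config$p_bout > 0) {
        plan_state <- c(plan_state, "forward"); plan_len <- c(plan_len, bout)
      } else {
        plan_state <- c(plan_state, "stationary"); plan_len <- c(plan_len, bout)
      }
      t <- t + bout
    }
    if (length(plan_len) == 0) {
      plan_state <- "stationary"; plan_len <- dur
    } else {
      plan_len[length(plan_len)] <- plan_len[length(plan_len)] + (dur - sum(plan_len))
    }
    too_short <- dur < config$immobility_duration_s$min + config$bout_duration_s$min
    if (config$p_bout > 0 && !any(plan_state == "forward") && (config$p_bout == 1 || too_short)) {
      stop("duration_s too short to place a single locomotion bout", call. = FALSE)
    }
    # merge adjacent stationary intervals
    keep_state <- character(0); keep_len <- numeric(0)
    for (i in seq_along(plan_state)) {
      if (length(keep_state) && plan_state[i] == "stationary" &&
          keep_state[length(keep_state)] == "stationary") {
        keep_len[length(keep_len)] <- keep_len[length(keep_len)] + plan_len[i]
      } else {
        keep_state <- c(keep_state, plan_state[i]); keep_len <- c(keep_len, plan_len[i])
      }
    }
    plan <- tibble(state = keep_state,
                   start_s = cumsum(c(0, head(keep_len, -1))),
                   end_s = cumsum(keep_len))

    # --- grooming epochs inside stationary intervals ---
    groom <- plan %>%
      filter(.data$state == "stationary", .data$end_s - .data$start_s > 1) %>%
      filter(runif(dplyr::n()) < config$grooming_prob) %>%
      mutate(g_on = .data$start_s + pmin(0.5, (.data$end_s - .data$start_s) / 3),
             g_off = .data$end_s)

    schedule <- plan
    if (nrow(groom)) {
      pieces <- purrr::pmap(plan, function(state, start_s, end_s) {
        g <- groom[groom$start_s == start_s & groom$end_s == end_s, ]
        if (state == "stationary" && nrow(g) == 1) {
          tibble(state = c("stationary", "grooming"),
                 start_s = c(start_s, g$g_on), end_s = c(g$g_on, end_s))
        } else tibble(state = state, start_s = start_s, end_s = end_s)
      })
      schedule <- list_rbind(pieces)
    }

    # --- analytic piecewise-linear speed profile ---
    # breakpoints (time, speed); ramps live inside forward intervals
    bt <- c(0); bv <- c(0)
    fwd <- plan %>% filter(.data$state == "forward")
    for (i in seq_len(nrow(fwd))) {
      a <- fwd$start_s[i]; b <- fwd$end_s[i]
      ramp <- min(config$ramp_s, (b - a) / 2)
      bt <- c(bt, a, a + ramp, b - ramp, b)
      bv <- c(bv, 0, config$run_speed_cms, config$run_speed_cms, 0)
    }
    bt <- c(bt, dur); bv <- c(bv, 0)
    # drop zero-length segments (e.g. triangular ramps, bouts abutting t = 0);
    # the profile is continuous so the duplicated value is redundant
    keep_bp <- c(TRUE, diff(bt) > 0)
    bt <- bt[keep_bp]; bv <- bv[keep_bp]

    rate <- config$behavior_rate_hz
    n <- floor(dur * rate) + 1L
    tt <- (seq_len(n) - 1L) / rate
    # position = integral of the piecewise-linear speed profile
    seg_area <- diff(bt) * (head(bv, -1) + tail(bv, -1)) / 2
    cum_area <- c(0, cumsum(seg_area))
    seg <- findInterval(tt, bt, rightmost.closed = TRUE)
    v_at <- approx(bt, bv, xout = tt, rule = 2)$y
    pos <- cum_area[seg] + (tt - bt[seg]) * (bv[seg] + v_at) / 2

    landmarks <- tibble(
      frame = seq_len(n) - 1L,
      time_s = tt,
      left_ear_x = pos, left_ear_y = 0.75,
      right_ear_x = pos, right_ear_y = -0.75,
      spine_x = pos - 2, spine_y = 0
    )
    speed <- oriented_speed(landmarks)

    # --- ground truth events from the emitted (classified) trace ---
    r <- rle(speed$state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    ev <- new_event_list()
    long_f <- sec_to_frames(3, rate)
    for (i in seq_len(max(0, length(r$lengths) - 1L))) {
      if (r$values[i] == "forward" && r$values[i + 1L] == "stationary") {
        on <- starts[i + 1L]
        off <- if (ends[i + 1L] + 1L <= n) tt[ends[i + 1L] + 1L] else NA_real_
        ev <- bind_rows(ev, new_event_list("stop", tt[on], on - 1L, off, "ground_truth"))
        if (r$lengths[i + 1L] >= long_f) {
          ev <- bind_rows(ev, new_event_list("long_stop", tt[on], on - 1L, off, "ground_truth"))
        }
      }
      if (r$values[i] == "stationary" && r$values[i + 1L] == "forward") {
        on <- starts[i + 1L]
        off <- if (ends[i + 1L] + 1L <= n) tt[ends[i + 1L] + 1L] else NA_real_
        ev <- bind_rows(ev, new_event_list("start", tt[on], on - 1L, off, "ground_truth"))
      }
    }
    gsched <- schedule %>% filter(.data$state == "grooming")
    if (nrow(gsched)) {
      ev <- bind_rows(ev, new_event_list(
        "grooming", gsched$start_s, sec_to_frames(gsched$start_s, rate),
        gsched$end_s, "ground_truth"
      ))
    }
    ev <- ev %>% arrange(.data$onset_s)

    structure(list(schedule = schedule, landmarks = landmarks, speed = speed,
                   events = ev, config = config),
              class = "behavior_sim")
  })
}

#' Simulate a planted cell's underlying rate
#'
#' Builds the rate time course (a.u./s, on the calcium clock) implied by a
#' ground-truth cell and a behaviour simulation. Excited classes sit at a low
#' baseline (0.2 a.u./s) and, with probability `reliability_p` per preferred
#' event, receive a rate bump of `response_amp` lasting 0.4 s (or the whole
#' following state when `sustained`). Stop-inhibited cells carry a tonic
#' baseline of 2 a.u./s suppressed to 5% for 1.25 s (or the whole state) at
#' responded stops. Uncorrelated cells receive event-independent bumps at
#' 0.1 events/s.
#'
#' @param behavior A `behavior_sim` from [simulate_behavior()].
#' @param cell A one-row ground-truth cell tibble ([ground_truth_cell()]).
#' @param seed Seed for the event-wise reliability draws.
#' @return A list: `rate` (numeric vector on the calcium clock), `time_s`,
#'   `responded` (tibble of preferred events with the realised response flag).
#' @export
simulate_cell_rate <- function(behavior, cell, seed = 1L) {
  stopifnot(inherits(behavior, "behavior_sim"), nrow(cell) == 1)
  config <- behavior$config
  rate_hz <- config$calcium_rate_hz
  n <- floor(config$duration_s * rate_hz) + 1L
  tt <- (seq_len(n) - 1L) / rate_hz
  bump_s <- 0.4
  baselines <- c(stop_excited = 0.2, start_excited = 0.2, grooming_excited = 0.2,
                 uncorrelated = 0.2, stop_inhibited = 2)
  base <- baselines[[cell$cell_class]]
  rate <- rep(base, n)
  preferred <- switch(cell$cell_class,
    stop_excited = , stop_inhibited = behavior$events %>% filter(.data$event == "stop"),
    start_excited = behavior$events %>% filter(.data$event == "start"),
    grooming_excited = behavior$events %>% filter(.data$event == "grooming"),
    uncorrelated = behavior$events[0, ]
  )
  with_seed(seed, {
    responded <- preferred
    if (nrow(preferred)) {
      hit <- runif(nrow(preferred)) < cell$reliability_p
      responded$responded <- hit
      for (i in which(hit)) {
        on <- sec_to_frames(preferred$onset_s[i], rate_hz) + 1L
        end_s <- if (cell$sustained && is.finite(preferred$offset_s[i])) {
          preferred$offset_s[i]
        } else if (cell$cell_class == "stop_inhibited") {
          preferred$onset_s[i] + 1.25
        } else {
          preferred$onset_s[i] + bump_s
        }
        off <- min(n, sec_to_frames(end_s, rate_hz))
        idx <- on:max(on, off)
        if (cell$cell_class == "stop_inhibited") {
          rate[idx] <- base * 0.05
        } else {
          rate[idx] <- rate[idx] + cell$response_amp
        }
      }
    } else {
      responded$responded <- logical(0)
    }
    if (cell$cell_class == "uncorrelated" && cell$response_amp > 0) {
      n_b <- rpois(1, 0.1 * config$duration_s)
      if (n_b > 0) {
        ons <- sort(runif(n_b, 0, config$duration_s - bump_s))
        for (o in ons) {
          idx <- (sec_to_frames(o, rate_hz) + 1L):min(n, sec_to_frames(o + bump_s, rate_hz))
          rate[idx] <- rate[idx] + cell$response_amp
        }
      }
    }
    list(rate = rate, time_s = tt, responded = responded)
  })
}

#' Calcium transient kernel
#'
#' Difference-of-exponentials transient shape
#' `k(t) = exp(-t / decay) - exp(-t / rise)` for `t >= 0` (0 before),
#' normalised to unit peak.
#'
#' @param t Times (s).
#' @param rise_s,decay_s Rise and decay constants (s), `decay_s > rise_s`.
#' @return Kernel values at `t`.
#' @export
calcium_kernel <- function(t, rise_s = 0.075, decay_s = 0.5) {
  stopifnot(decay_s > rise_s, rise_s > 0)
  t_peak <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  peak <- exp(-t_peak / decay_s) - exp(-t_peak / rise_s)
  ifelse(t >= 0, (exp(-t / decay_s) - exp(-t / rise_s)) / peak, 0)
}

#' Deterministic event train to calcium trace
#'
#' Convolves a train of point events (frame index, amplitude) with the
#' unit-peak transient kernel and adds white noise. This is the deterministic
#' core of [rate_to_calcium()]; with `noise_sd = 0` the output is the exact
#' superposition of kernels.
#'
#' @param onset_frames Integer 0-based frame indices of the events.
#' @param amplitudes Event amplitudes (recycled).
#' @param n_frames Output length in frames.
#' @param config A [sim_config()] (kernel constants, rate, noise level).
#' @param noise_sd Override for `config$noise_sd`.
#' @param seed Seed for the noise draw.
#' @return A trace tibble `time_s`, `dff`.
#' @export
events_to_calcium <- function(onset_frames, amplitudes, n_frames, config,
                              noise_sd = config$noise_sd, seed = NULL) {
  rate_hz <- config$calcium_rate_hz
  impulses <- numeric(n_frames)
  if (length(onset_frames)) {
    amplitudes <- rep_len(amplitudes, length(onset_frames))
    for (i in seq_along(onset_frames)) {
      f <- onset_frames[i] + 1L
      if (f >= 1 && f <= n_frames) impulses[f] <- impulses[f] + amplitudes[i]
    }
  }
  kt <- seq(0, by = 1 / rate_hz, length.out = n_frames)
  k <- calcium_kernel(kt, config$kernel_rise_s, config$kernel_decay_s)
  support <- max(which(k > 1e-12), 2L)
  k <- k[seq_len(support)]
  y <- convolve(impulses, rev(k), type = "open")[seq_len(n_frames)]
  if (noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(n_frames, sd = noise_sd))
  }
  tibble(time_s = (seq_len(n_frames) - 1L) / rate_hz, dff = y)
}

#' Rate time course to noisy calcium trace
#'
#' Draws Poisson point events from a nonnegative rate (events per second,
#' per-frame probability `rate * dt`), convolves them with the unit-peak
#' difference-of-exponentials kernel and adds Gaussian white noise of
#' standard deviation `config$noise_sd`.
#'
#' @param rate Nonnegative numeric vector, a.u./s on the calcium clock.
#' @param config A [sim_config()].
#' @param seed Seed governing both the Poisson draw and the noise.
#' @return A trace tibble `time_s`, `dff`.
#' @export
rate_to_calcium <- function(rate, config, seed = 1L) {
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("rate must be finite and nonnegative", call. = FALSE)
  }
  dt <- 1 / config$calcium_rate_hz
  with_seed(seed, {
    counts <- rpois(length(rate), rate * dt)
    on <- which(counts > 0)
    events_to_calcium(on - 1L, counts[on], length(rate), config,
                      noise_sd = config$noise_sd, seed = NULL)
  })
}

#' Simulate a full coupled dataset
#'
#' Runs [simulate_behavior()] and generates one calcium trace per planted
#' cell, with per-cell seeds derived from the configuration seed.
#'
#' @param config A [sim_config()].
#' @param cells Ground-truth cell tibble (e.g. [default_cohort()]).
#' @return A list of class `sim_dataset`: `behavior` (a `behavior_sim`),
#'   `traces` (wide tibble `time_s` + one column per cell), `cells`,
#'   `events` (ground truth), `config`.
#' @export
simulate_dataset <- function(config, cells = default_cohort()) {
  behavior <- simulate_behavior(config)
  traces <- NULL
  for (i in seq_len(nrow(cells))) {
    cr <- simulate_cell_rate(behavior, cells[i, ], seed = config$seed + 1000L + i)
    tr <- rate_to_calcium(cr$rate, config, seed = config$seed + 2000L + i)
    if (is.null(traces)) traces <- tibble(time_s = tr$time_s)
    traces[[cells$cell_id[i]]] <- tr$dff
  }
  if (is.null(traces)) {
    n <- floor(config$duration_s * config$calcium_rate_hz) + 1L
    traces <- tibble(time_s = (seq_len(n) - 1L) / config$calcium_rate_hz)
  }
  attr(traces, "rate_hz") <- config$calcium_rate_hz
  structure(list(behavior = behavior, traces = traces, cells = cells,
                 events = behavior$events, config = config),
            class = "sim_dataset")
}
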