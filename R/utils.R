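# Shared internal helpers: frame/time conversion, valid periods, seeding.

# Convert a duration in seconds to a whole number of frames, rounding
# half-up (0.25 s at 50 Hz -> 13 frames). Detection criteria are evaluated
# at frame resolution throughout.
sec_to_frames <- function(x, rate_hz) {
  as.integer(floor(x * rate_hz + 0.5))
}

# Sampling rate of a trace-like tibble with a time_s column.
infer_rate <- function(time_s) {
  if (length(time_s) < 2) stop("need at least 2 samples to infer a rate", call. = FALSE)
  dt <- diff(time_s)
  if (any(!is.finite(dt)) || any(dt <= 0)) {
    stop("time_s must be finite and strictly increasing", call. = FALSE)
  }
  if (max(dt) - min(dt) > 1e-6 * median(dt)) {
    stop("time_s must be uniformly sampled", call. = FALSE)
  }
  1 / median(dt)
}

# Validate a valid-periods table (columns start_s, end_s); NULL passes through.
check_valid_periods <- function(valid_periods) {
  if (is.null(valid_periods)) return(NULL)
  vp <- as_tibble(valid_periods)
  if (!all(c("start_s", "end_s") %in% names(vp))) {
    stop("valid_periods needs columns start_s and end_s", call. = FALSE)
  }
  if (any(vp$end_s <= vp$start_s)) {
    stop("valid_periods must have end_s > start_s", call. = FALSE)
  }
  vp
}

# Membership of times in the union of half-open periods [start_s, end_s).
in_valid_periods <- function(times, valid_periods) {
  if (is.null(valid_periods)) return(rep(TRUE, length(times)))
  vp <- check_valid_periods(valid_periods)
  out <- rep(FALSE, length(times))
  for (i in seq_len(nrow(vp))) {
    out <- out | (times >= vp$start_s[i] & times < vp$end_s[i])
  }
  out
}

# Run a block with a locally-set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical event-list tibble used by all detectors and the simulator.
new_event_list <- function(event = character(), onset_s = numeric(),
                           onset_frame = integer(), offset_s = numeric(),
                           provenance = character()) {
  tibble(
    event = as.character(event),
    onset_s = as.numeric(onset_s),
    onset_frame = as.integer(onset_frame),
    offset_s = as.numeric(offset_s),
    provenance = as.character(provenance)
  )
}

event_types <- c("stop", "long_stop", "start", "grooming")

# Extract the value matrix (frames x cells) and cell ids from a wide trace
# tibble (time_s + one numeric column per cell).
trace_matrix <- function(traces) {
  stopifnot(is.data.frame(traces), "time_s" %in% names(traces))
  cells <- setdiff(names(traces), c("frame", "time_s"))
  x <- as.matrix(traces[, cells, drop = FALSE])
  if (!is.numeric(x)) stop("trace columns must be numeric", call. = FALSE)
  list(x = x, cells = cells, time_s = traces$time_s)
}

# Coerce trace input: either a numeric vector (rate_hz required) or a
# two-column tibble time_s + value column. Returns list(values, rate_hz, time_s).
as_trace <- function(trace, rate_hz = NULL, value_col = "dff") {
  if (is.numeric(trace) && is.null(dim(trace))) {
    if (is.null(rate_hz)) stop("rate_hz is required when trace is a bare vector", call. = FALSE)
    n <- length(trace)
    return(list(values = as.numeric(trace), rate_hz = rate_hz,
                time_s = seq(0, by = 1 / rate_hz, length.out = n)))
  }
  stopifnot(is.data.frame(trace), "time_s" %in% names(trace))
  vcol <- if (value_col %in% names(trace)) value_col else setdiff(names(trace), c("frame", "time_s"))[1]
  if (is.na(vcol)) stop("trace has no value column", call. = FALSE)
  rate <- infer_rate(trace$time_s)
  list(values = as.numeric(trace[[vcol]]), rate_hz = rate, time_s = trace$time_s)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
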