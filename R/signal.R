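# Trace-level processing of calcium signals: dF/F normalisation, Gaussian
# smoothing and first-order deconvolution of the indicator decay. All three
# operations are linear and accept either a bare numeric vector (with
# rate_hz where needed) or a wide trace tibble (time_s + one column per cell),
# in which case each cell column is processed and the shape preserved.

apply_per_cell <- function(traces, fun, variant) {
  if (is.numeric(traces) && is.null(dim(traces))) {
    out <- fun(as.numeric(traces))
    attr(out, "variant") <- variant
    return(out)
  }
  stopifnot(is.data.frame(traces))
  tm <- trace_matrix(traces)
  out <- traces
  for (cell in tm$cells) out[[cell]] <- fun(as.numeric(traces[[cell]]))
  attr(out, "variant") <- variant
  attr(out, "rate_hz") <- attr(traces, "rate_hz") %||% infer_rate(traces$time_s)
  out
}

#' dF/F normalisation
#'
#' Normalises a raw fluorescence trace by its time-averaged mean:
#' `out = in / mean(in) - 1`. The output is dimensionless with zero mean.
#'
#' @param traces Raw fluorescence: numeric vector or wide tibble
#'   (`time_s` + one column per cell).
#' @return Same shape as the input, tagged with variant `"raw"` (dF/F).
#' @export
#' @examples
#' dff_normalize(c(1, 3, 1, 3))  # -0.5, 0.5, -0.5, 0.5
dff_normalize <- function(traces) {
  apply_per_cell(traces, function(x) {
    m <- mean(x)
    if (!is.finite(m) || m <= 0) {
      stop("cannot compute dF/F: trace mean must be positive", call. = FALSE)
    }
    x / m - 1
  }, variant = "raw")
}

#' Gaussian smoothing of calcium traces
#'
#' Convolution with a unit-area truncated Gaussian kernel. The kernel width is
#' given as the half-width at half-maximum (`half_width_s`, default 150 ms),
#' i.e. sigma = half_width / sqrt(2 ln 2). Near the edges the kernel is
#' renormalised over its valid support, so constant traces pass unchanged
#' everywhere.
#'
#' @param traces Numeric vector or wide trace tibble.
#' @param half_width_s Half-width at half-maximum of the kernel (s).
#' @param rate_hz Sampling rate; required for bare vectors, inferred from
#'   `time_s` otherwise.
#' @param truncate Kernel support in units of sigma (default 4).
#' @return Smoothed traces, same shape, variant `"smoothed"`.
#' @export
gaussian_smooth <- function(traces, half_width_s = 0.15, rate_hz = NULL, truncate = 4) {
  rate <- rate_hz %||% if (is.data.frame(traces)) infer_rate(traces$time_s) else
    stop("rate_hz is required for bare vectors", call. = FALSE)
  sigma_f <- (half_width_s / sqrt(2 * log(2))) * rate
  half <- max(1L, ceiling(truncate * sigma_f))
  k <- exp(-0.5 * ((-half:half) / sigma_f)^2)
  k <- k / sum(k)
  apply_per_cell(traces, function(x) {
    n <- length(x)
    if (n < length(k)) stop("trace shorter than the smoothing kernel support", call. = FALSE)
    # zero-padded convolution; dividing by the convolved all-ones signal
    # renormalises the kernel over its in-bounds support at the edges
    num <- conv_open(x, k)
    den <- conv_open(rep(1, n), k)
    num / den
  }, variant = "smoothed")
}

# Full (zero-padded) linear convolution of x with symmetric kernel k,
# trimmed back to length(x) with the kernel centred.
conv_open <- function(x, k) {
  half <- (length(k) - 1L) %/% 2L
  full <- convolve(x, rev(k), type = "open")
  full[(half + 1L):(half + length(x))]
}

#' First-order deconvolution of the indicator decay
#'
#' Estimates the underlying rate time course from a calcium trace by
#' cancelling the indicator's exponential decay: `S_d = tau * dS/dt + S`,
#' with the derivative taken by central differences (one-sided at the edges).
#' `tau` defaults to 0.5 s, a typical GCaMP6s decay time. The central
#' difference makes the estimate lag-symmetric; the indicator's 50-100 ms
#' rise time is not cancelled, so the output still lags the true rate by up
#' to two frames at 20 Hz.
#'
#' @param traces Numeric vector or wide trace tibble.
#' @param tau_s Indicator decay time constant (s), must be positive.
#' @param rate_hz Sampling rate; required for bare vectors.
#' @return Deconvolved traces, same shape, variant `"deconvolved"`.
#' @export
deconvolve <- function(traces, tau_s = 0.5, rate_hz = NULL) {
  if (!is.numeric(tau_s) || tau_s <= 0) stop("tau_s must be positive", call. = FALSE)
  rate <- rate_hz %||% if (is.data.frame(traces)) infer_rate(traces$time_s) else
    stop("rate_hz is required for bare vectors", call. = FALSE)
  dt <- 1 / rate
  apply_per_cell(traces, function(x) {
    n <- length(x)
    if (n < 3) stop("trace too short to deconvolve", call. = FALSE)
    d <- numeric(n)
    d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
    d[1] <- (x[2] - x[1]) / dt
    d[n] <- (x[n] - x[n - 1]) / dt
    tau_s * d + x
  }, variant = "deconvolved")
}
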