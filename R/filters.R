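# Filtering stages: zero-phase Butterworth band filtering and the
# subtractive 60 Hz notch built on median-scaling.

trace_values <- function(trace) {
  if (is.numeric(trace)) trace else trace$values
}

set_trace_values <- function(trace, values) {
  if (is.numeric(trace)) return(values)
  trace$values <- values
  trace
}

#' Zero-phase Butterworth filtering of an epoch
#'
#' Applies a second-order Butterworth filter forward and backward
#' (zero-phase, preserving peak latencies) to the pulse-averaged epoch. A
#' short guard period (`trim_ms`, default 2 ms) at each end of the epoch is
#' excluded from filtering — it contains the stimulation pulse and the edge
#' transients of epoch averaging — and is restored as zeros.
#'
#' @param trace An `averaged_trace`, `zscored_trace`, or numeric vector.
#' @param low_hz High-pass corner (attenuates below), or `NULL`.
#' @param high_hz Low-pass corner (attenuates above), or `NULL`.
#' @param fs_hz Sampling rate; taken from the trace object when present.
#' @param trim_ms Guard period excluded at each end, ms.
#' @return Same type as `trace`.
#' @export
butter_zero_phase <- function(trace, low_hz = NULL, high_hz = NULL,
                              fs_hz = NULL, trim_ms = 2) {
  x <- trace_values(trace)
  if (is.null(fs_hz)) fs_hz <- trace$fs_hz
  nyq <- fs_hz / 2
  if (is.null(low_hz) && is.null(high_hz)) {
    stop_mep("supply low_hz and/or high_hz", "mep_invalid_band")
  }
  for (edge in c(low_hz, high_hz)) {
    if (edge <= 0 || edge >= nyq) {
      stop_mep("band edges must lie in (0, fs/2)", "mep_invalid_band")
    }
  }
  n <- length(x)
  k <- ms_to_samples(trim_ms, fs_hz)
  if (n - 2 * k < 12) {
    stop_mep("epoch too short for the requested trim", "mep_short_epoch")
  }
  core <- (k + 1L):(n - k)
  z <- x[core]
  # band filtering runs the two second-order sections in cascade: the
  # combined 4th-order transfer function is numerically ill-conditioned
  # when the high-pass corner sits far below Nyquist
  if (!is.null(low_hz)) {
    bf <- signal::butter(2, low_hz / nyq, type = "high")
    z <- filtfilt_steady(bf$b, bf$a, z)
  }
  if (!is.null(high_hz)) {
    bf <- signal::butter(2, high_hz / nyq, type = "low")
    z <- filtfilt_steady(bf$b, bf$a, z)
  }
  y <- numeric(n)                       # trimmed samples restored as zeros
  y[core] <- z
  set_trace_values(trace, y)
}

# Steady-state initial conditions for a direct-form-II-transposed filter:
# the state vector that makes a constant input produce a constant output
# immediately (no startup transient).
lfilter_zi <- function(b, a) {
  n <- length(a)
  companion <- rbind(-a[2:n] / a[1], cbind(diag(n - 2), 0))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(companion), B)
}

lfilter_state <- function(b, a, x, zi) {
  y <- numeric(length(x))
  z <- zi
  nb <- length(b)
  m <- length(z)
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + z[1]
    if (m > 1) {
      for (j in seq_len(m - 1)) {
        z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * y[i]
      }
    }
    z[m] <- b[nb] * x[i] - a[nb] * y[i]
  }
  y
}

# Forward-backward filtering with odd-reflection padding and steady-state
# initialization at both ends, so DC offsets and slow components near the
# epoch edges leave no startup transient.
filtfilt_steady <- function(b, a, x) {
  n <- length(x)
  padlen <- n - 1L
  ext <- c(2 * x[1] - x[(padlen + 1):2], x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  zi <- lfilter_zi(b, a)
  y <- lfilter_state(b, a, ext, zi * ext[1])
  y <- rev(lfilter_state(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

#' Median-scaling template fit
#'
#' Robust amplitude fit of a template to a target: the scale is the median
#' of the element-wise ratio `target / template`, ignoring samples where the
#' template is near zero (|template| < eps * max|template|). Because the
#' median discounts sparse, short-duration excursions, a temporally sparse
#' evoked response riding on the target barely influences the fitted scale —
#' the property the subtractive notch and the artifact-rejection stages rely
#' on.
#'
#' @param target,template Equal-length numeric vectors.
#' @param eps Relative threshold below which template samples are excluded
#'   from the median.
#' @return The fitted scale (a single number).
#' @export
#' @examples
#' tmpl <- sin(seq(0, 4 * pi, length.out = 200))
#' median_scale_fit(3 * tmpl, tmpl)
median_scale_fit <- function(target, template, eps = 1e-3) {
  stopifnot(length(target) == length(template))
  mx <- max(abs(template))
  if (mx == 0) {
    stop_mep("template is identically zero", "mep_degenerate_template")
  }
  valid <- abs(template) >= eps * mx
  if (sum(valid) < 8) {
    stop_mep("fewer than 8 valid samples for median-scaling",
             "mep_degenerate_template")
  }
  stats::median(target[valid] / template[valid])
}

# Phase of the f0 component. A 100 ms epoch (10 Hz stimulation) makes 60 Hz
# an exact FFT bin; for other epoch lengths a direct single-frequency
# projection at exactly f0 is used instead so the estimate never leaks
# across bins.
component_phase <- function(x, fs_hz, f0_hz) {
  n <- length(x)
  k <- f0_hz * n / fs_hz
  if (abs(k - round(k)) < 1e-9) {
    # sine convention: x = A sin(wt + phi) has FFT angle phi - pi/2 at bin k
    Arg(stats::fft(x)[round(k) + 1L]) + pi / 2
  } else {
    t <- (seq_len(n) - 1) / fs_hz
    a <- sum(x * sin(2 * pi * f0_hz * t))
    b <- sum(x * cos(2 * pi * f0_hz * t))
    atan2(b, a)
  }
}

#' Subtractive line-noise removal
#'
#' Removes the 60 Hz line component by fitting and subtracting a sinusoid in
#' the time domain rather than by convolutional notch filtering: the phase
#' comes from the Fourier transform of the epoch, and the sinusoid's
#' amplitude is fitted by median-scaling (see [median_scale_fit()]) so that
#' a temporally sparse evoked response does not distort the fit. Because a
#' large sparse response also leaks into the 60 Hz Fourier bin and biases
#' the phase estimate, the fit alternates a few robust refinement steps: a
#' DC term (the ratio median is unstable in the presence of an offset), the
#' in-phase amplitude, and the quadrature amplitude are each re-fitted by
#' the median rule until the subtracted component — still a single 60 Hz
#' sinusoid — absorbs the phase-estimation error. Only the fundamental is
#' removed; harmonics are shorter in period and lower in magnitude than
#' evoked responses and do not affect detection.
#'
#' @param trace An `averaged_trace`, `zscored_trace`, or numeric vector.
#' @param f0_hz Line frequency (default 60).
#' @param fs_hz Sampling rate; taken from the trace object when present.
#' @param refinements Number of robust refinement sweeps (default 3).
#' @return Same type as `trace`, with the fitted sinusoid subtracted. The
#'   fitted amplitude is attached as attribute `"notch_scale"`.
#' @export
subtractive_notch <- function(trace, f0_hz = 60, fs_hz = NULL,
                              refinements = 3) {
  x <- trace_values(trace)
  if (is.null(fs_hz)) fs_hz <- trace$fs_hz
  n <- length(x)
  if (n / fs_hz < 1 / f0_hz) {
    stop_mep("epoch shorter than one period of f0", "mep_short_epoch")
  }
  phi <- component_phase(x, fs_hz, f0_hz)
  t <- (seq_len(n) - 1) / fs_hz
  s1 <- sin(2 * pi * f0_hz * t + phi)
  c1 <- cos(2 * pi * f0_hz * t + phi)
  A <- 0; B <- 0; o <- 0
  for (i in seq_len(refinements)) {
    o <- o + stats::median(x - A * s1 - B * c1 - o)
    A <- A + median_scale_fit(x - A * s1 - B * c1 - o, s1)
    B <- B + median_scale_fit(x - A * s1 - B * c1 - o, c1)
  }
  out <- set_trace_values(trace, x - A * s1 - B * c1)
  attr(out, "notch_scale") <- sqrt(A^2 + B^2)
  out
}
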