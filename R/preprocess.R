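#' Pulse-triggered averaging
#'
#' Averages the period following each stimulation pulse into one epoch per
#' channel (e.g. a 100 ms trace for 10 Hz stimulation). Epochs are truncated
#' at the next pulse onset; an incomplete final epoch is discarded. Averaging
#' across pulses suppresses noise uncorrelated with the pulse train by
#' `1/sqrt(n_pulses)` while preserving pulse-locked components (the evoked
#' response, the recovery artifact, and — because 60 Hz is periodic in the
#' 100 ms epoch — line noise).
#'
#' @param rec A [raw_recording()].
#' @param max_duration_s If set, only pulses with onset before this time are
#'   averaged (used for stimulation-duration sweeps).
#' @return A traces tibble: one row per channel with columns `subject_id`,
#'   `setting_id`, `label`, `group`, `laterality`, and a list-column `trace`
#'   of `averaged_trace` objects (`values` in microvolts, `fs_hz`,
#'   `n_pulses`, `channel`).
#' @export
epoch_average <- function(rec, max_duration_s = NULL) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs_hz
  epoch_len <- round(fs / rec$setting$frequency_hz)
  onsets <- rec$pulse_onsets
  if (!is.null(max_duration_s)) {
    onsets <- onsets[(onsets - 1) / fs < max_duration_s]
  }
  # truncate at the next onset; drop epochs running past the recording
  if (length(onsets) > 1L) {
    epoch_len <- min(epoch_len, min(diff(rec$pulse_onsets)))
  }
  n <- ncol(rec$signal)
  onsets <- onsets[onsets + epoch_len - 1L <= n]
  if (length(onsets) == 0L) {
    stop_mep("no complete epoch fits after the first pulse onset",
             "mep_no_epochs")
  }
  idx <- outer(onsets, 0:(epoch_len - 1L), `+`)   # n_pulses x epoch_len
  traces <- lapply(seq_len(nrow(rec$signal)), function(ci) {
    epochs <- matrix(rec$signal[ci, idx], nrow = length(onsets))
    structure(
      list(
        values = colMeans(epochs),
        fs_hz = fs,
        frequency_hz = rec$setting$frequency_hz,
        n_pulses = length(onsets),
        channel = rec$channels[ci, ]
      ),
      class = "averaged_trace"
    )
  })
  tibble::tibble(
    subject_id = rec$subject_id,
    setting_id = rec$setting$setting_id,
    label = rec$channels$label,
    group = rec$channels$group,
    laterality = rec$channels$laterality,
    trace = traces
  )
}

#' @export
print.averaged_trace <- function(x, ...) {
  cat(sprintf("<averaged_trace> %s: %d samples @ %g kHz, mean of %d pulses\n",
              x$channel$label, length(x$values), x$fs_hz / 1000, x$n_pulses))
  invisible(x)
}

# Baseline window: the trailing 10% of the epoch (10 ms of a 100 ms epoch at
# 10 Hz stimulation), assumed inert — late enough that the evoked response
# and the recovery artifact have ended.
baseline_window_idx <- function(n) {
  nb <- max(2L, round(0.1 * n))
  (n - nb + 1L):n
}

#' Baseline z-scoring of an averaged trace
#'
#' Computes the median and standard deviation over the inert baseline at the
#' end of the epoch and transforms the whole trace to z units:
#' `(values - median) / sd`. Rectification is deliberately not applied here;
#' the detector rectifies.
#'
#' @param trace An `averaged_trace` from [epoch_average()].
#' @return A `zscored_trace`: `values` (z units), `baseline_median_uv`,
#'   `baseline_sd_uv`, plus the provenance fields of the input.
#' @export
baseline_zscore <- function(trace) {
  stopifnot(inherits(trace, "averaged_trace"))
  v <- trace$values
  n <- length(v)
  if (n / trace$fs_hz * 1000 < 20) {
    stop_mep("epoch shorter than 20 ms; no usable baseline", "mep_short_epoch")
  }
  bl <- v[baseline_window_idx(n)]
  med <- stats::median(bl)
  sd <- stats::sd(bl)
  if (!is.finite(sd) || sd <= 0) {
    stop_mep(sprintf("degenerate baseline (sd = 0) on channel %s",
                     trace$channel$label), "mep_degenerate_baseline")
  }
  structure(
    list(
      values = (v - med) / sd,
      baseline_median_uv = med,
      baseline_sd_uv = sd,
      fs_hz = trace$fs_hz,
      frequency_hz = trace$frequency_hz,
      n_pulses = trace$n_pulses,
      channel = trace$channel
    ),
    class = "zscored_trace"
  )
}

#' @export
print.zscored_trace <- function(x, ...) {
  cat(sprintf("<zscored_trace> %s: baseline median %.3g uV, sd %.3g uV\n",
              x$channel$label, x$baseline_median_uv, x$baseline_sd_uv))
  invisible(x)
}

#' Noisy-channel exclusion rule
#'
#' A pulse-averaged trace is discarded when its variance over the late
#' (50-100 ms) window exceeds `var_threshold` (in microvolts squared) or its
#' mean absolute value over the whole epoch exceeds `abs_threshold`
#' microvolts — the signatures of detached electrodes, poor skin contact, or
#' movement contamination. For epochs shorter than 100 ms the variance
#' window is the second half of the epoch, preserving the proportions of the
#' 100 ms reference epoch.
#'
#' @param trace An `averaged_trace`.
#' @param var_threshold Variance threshold over the late window (150, in
#'   microvolts squared).
#' @param abs_threshold Mean-absolute-value threshold over the epoch (25
#'   microvolts).
#' @return `TRUE` if the trace should be excluded.
#' @export
apply_exclusion <- function(trace, var_threshold = 150, abs_threshold = 25) {
  stopifnot(inherits(trace, "averaged_trace"))
  v <- trace$values
  n <- length(v)
  epoch_ms <- n / trace$fs_hz * 1000
  if (epoch_ms >= 100) {
    win <- window_idx(n, trace$fs_hz, c(50, 100))
  } else {
    win <- (floor(n / 2) + 1L):n
  }
  stats::var(v[win]) > var_threshold || mean(abs(v)) > abs_threshold
}
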