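#' Assemble a raw multi-channel EMG recording
#'
#' Bundles the signal matrix for one stimulation trial with its pulse onset
#' times, channel metadata, and stimulation setting, and validates the whole
#' object. Pulse onsets are stored as 1-based sample indices (sample `i`
#' corresponds to `(i - 1) / fs_hz` seconds); on-disk metadata uses 0-based
#' indices and is converted at the I/O boundary.
#'
#' @param signal Numeric matrix `[n_channels x n_samples]`, in microvolts.
#' @param fs_hz Sampling rate in Hz (default 22000).
#' @param pulse_onsets Strictly increasing 1-based sample indices of
#'   stimulation pulse onsets.
#' @param channels Tibble of channel metadata, one row per signal row, as
#'   returned by [muscle_channel()] / [default_muscles()].
#' @param setting A [stim_setting()].
#' @param subject_id,lead_id Opaque identifiers.
#' @return A list with class `"raw_recording"`.
#' @export
raw_recording <- function(signal, fs_hz = 22000, pulse_onsets, channels,
                          setting, subject_id = "S1", lead_id = "L1") {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop_mep("signal must be a numeric matrix [n_channels x n_samples]",
             "mep_invalid_signal")
  }
  check_scalar(fs_hz, "fs_hz", positive = TRUE)
  if (!inherits(setting, "stim_setting")) {
    stop_mep("setting must be a stim_setting", "mep_invalid_setting")
  }
  if (nrow(signal) != nrow(channels)) {
    stop_mep(sprintf("channel metadata lists %d channels but signal has %d rows",
                     nrow(channels), nrow(signal)),
             "mep_channel_mismatch")
  }
  n <- ncol(signal)
  pulse_onsets <- as.integer(pulse_onsets)
  if (length(pulse_onsets) < 1L || any(pulse_onsets < 1L) ||
      any(pulse_onsets > n)) {
    stop_mep("pulse_onsets must be 1-based indices within the recording",
             "mep_invalid_onsets")
  }
  if (is.unsorted(pulse_onsets, strictly = TRUE)) {
    stop_mep("pulse_onsets must be strictly increasing", "mep_invalid_onsets")
  }
  expected_gap <- fs_hz / setting$frequency_hz
  if (length(pulse_onsets) > 1L) {
    gaps <- diff(pulse_onsets)
    if (any(abs(gaps - expected_gap) > 0.01 * expected_gap)) {
      stop_mep("pulse onset spacing deviates >1% from fs_hz / frequency_hz",
               "mep_invalid_onsets")
    }
  }
  rownames(signal) <- channels$label
  structure(
    list(
      signal = signal,
      fs_hz = fs_hz,
      pulse_onsets = pulse_onsets,
      channels = channels,
      setting = setting,
      subject_id = as.character(subject_id),
      lead_id = as.character(lead_id)
    ),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %s/%s setting %s: %d channels x %d samples @ %g kHz, %d pulses\n",
    x$subject_id, x$lead_id, x$setting$setting_id,
    nrow(x$signal), ncol(x$signal), x$fs_hz / 1000, length(x$pulse_onsets)
  ))
  cat("  channels:", paste(x$channels$label, collapse = ", "), "\n")
  invisible(x)
}

#' Detect pulse onsets from a stimulus-sync channel
#'
#' Absolute-threshold crossing with a refractory period of half the
#' inter-pulse interval, for recordings where onset times were not logged by
#' the stimulator but a sync channel carries the stimulus waveform.
#'
#' @param sync Numeric vector, the sync-channel signal.
#' @param fs_hz Sampling rate in Hz.
#' @param frequency_hz Pulse train frequency in Hz (sets the refractory
#'   period to half the inter-pulse interval).
#' @param threshold Absolute amplitude threshold; defaults to half the
#'   maximum absolute value of the channel.
#' @return Integer vector of 1-based onset sample indices.
#' @export
detect_pulse_onsets <- function(sync, fs_hz, frequency_hz = 10,
                                threshold = NULL) {
  if (is.null(threshold)) threshold <- 0.5 * max(abs(sync))
  refractory <- floor(fs_hz / frequency_hz / 2)
  above <- which(abs(sync) >= threshold)
  if (length(above) == 0L) {
    stop_mep("no threshold crossings found on sync channel", "mep_no_onsets")
  }
  onsets <- above[1]
  for (i in above) {
    if (i - onsets[length(onsets)] > refractory) onsets <- c(onsets, i)
  }
  onsets
}
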