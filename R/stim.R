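#' Describe a stimulation setting
#'
#' A DBS stimulation setting: current amplitude, pulse width, train frequency
#' and duration, and the active contact configuration in the geometric naming
#' scheme (levels 1 = most ventral to 4 = most dorsal; optional segment
#' A = anterior, M = posteromedial, L = posterolateral; a bipolar pair is
#' written `"3A-2A"`).
#'
#' @param amplitude_ma Stimulation amplitude in mA (> 0).
#' @param pulse_width_us First-phase pulse width in microseconds (> 0).
#' @param frequency_hz Pulse train frequency in Hz; 10 Hz by default so that
#'   each inter-pulse epoch (100 ms) comfortably contains the evoked response.
#' @param duration_s Train duration in seconds (default 12).
#' @param contact_config Contact configuration string, e.g. `"2"`, `"2L"`,
#'   `"3A-2A"`.
#' @param setting_id Opaque identifier; autogenerated when `NULL`.
#' @return A list with class `"stim_setting"`.
#' @export
#' @examples
#' stim_setting(3, contact_config = "2L")
stim_setting <- function(amplitude_ma,
                         pulse_width_us = 60,
                         frequency_hz = 10,
                         duration_s = 12,
                         contact_config = "2",
                         setting_id = NULL) {
  check_scalar(amplitude_ma, "amplitude_ma", positive = TRUE)
  check_scalar(pulse_width_us, "pulse_width_us", positive = TRUE)
  check_scalar(frequency_hz, "frequency_hz", positive = TRUE)
  check_scalar(duration_s, "duration_s", positive = TRUE)
  if (frequency_hz * duration_s < 1) {
    stop_mep("frequency_hz * duration_s must be >= 1 (at least one pulse)",
             "mep_invalid_setting")
  }
  if (!grepl("^[1-4][AML]?(-[1-4][AML]?)?$", contact_config)) {
    stop_mep(
      sprintf("contact_config '%s' does not parse (levels 1-4, segments A/M/L, e.g. '2L' or '3A-2A')",
              contact_config),
      "mep_invalid_contact"
    )
  }
  if (is.null(setting_id)) {
    setting_id <- sprintf("%s_%gmA_%gus", contact_config, amplitude_ma,
                          pulse_width_us)
  }
  structure(
    list(
      amplitude_ma = amplitude_ma,
      pulse_width_us = pulse_width_us,
      frequency_hz = frequency_hz,
      duration_s = duration_s,
      contact_config = contact_config,
      setting_id = as.character(setting_id)
    ),
    class = "stim_setting"
  )
}

#' @export
print.stim_setting <- function(x, ...) {
  cat(sprintf("<stim_setting> %s: %g mA, %g us, %g Hz x %g s\n",
              x$setting_id, x$amplitude_ma, x$pulse_width_us,
              x$frequency_hz, x$duration_s))
  invisible(x)
}

#' Render the stimulus pulse waveform
#'
#' The asymmetric charge-balanced biphasic pulse used clinically: a first
#' phase of width `pulse_width_us` at unit (normalized) amplitude, a 70 us
#' inter-phase gap, then an opposite-polarity second phase. For pulse widths
#' up to 60 us the second phase is 8x longer at 1/8 amplitude; wider pulses
#' have the second phase capped at 480 us with its amplitude raised to keep
#' the phases charge-balanced.
#'
#' Used only to render an optional stimulus-sync channel in the simulator;
#' EMG channels see the amplifier-recovery artifact instead.
#'
#' @param setting A [stim_setting()].
#' @param fs_hz Sampling rate in Hz.
#' @return Numeric vector, one pulse at unit first-phase amplitude.
#' @export
stim_pulse_waveform <- function(setting, fs_hz) {
  pw_s <- setting$pulse_width_us * 1e-6
  gap_s <- 70e-6
  if (setting$pulse_width_us <= 60) {
    pw2_s <- 8 * pw_s
    amp2 <- 1 / 8
  } else {
    pw2_s <- 480e-6
    amp2 <- pw_s / pw2_s   # charge balance: amp2 * pw2 = 1 * pw
  }
  n1 <- max(1L, ms_to_samples(pw_s * 1000, fs_hz))
  ng <- ms_to_samples(gap_s * 1000, fs_hz)
  n2 <- max(1L, ms_to_samples(pw2_s * 1000, fs_hz))
  c(rep(1, n1), rep(0, ng), rep(-amp2, n2))
}
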