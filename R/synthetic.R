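#' Synthetic mEP waveform kernel
#'
#' Generates one epoch-length motor-evoked-potential waveform as a seeded
#' mixture of 2-3 Gaussian-shaped lobes: a dominant lobe at the requested
#' latency plus one or two smaller opposite-sign side lobes, giving the
#' biphasic shape characteristic of surface-recorded compound muscle
#' potentials. The kernel is fixed by `waveform_seed`, so a (subject, muscle)
#' pair keeps the same waveform across stimulation settings — the
#' within-subject stereotypy observed in real recordings.
#'
#' The largest absolute excursion equals `amplitude_uv` and occurs at
#' `latency_ms`; the dominant lobe's full width at half maximum is
#' `width_ms` (within ~10%); the kernel is identically zero outside
#' `[latency - 2 width, latency + 3 width]`.
#'
#' @param n_samples Epoch length in samples.
#' @param fs_hz Sampling rate in Hz.
#' @param latency_ms Peak latency in ms after the pulse.
#' @param amplitude_uv Peak absolute amplitude in microvolts (0 gives an
#'   all-zero kernel).
#' @param width_ms Dominant-lobe full width at half maximum, ms (1-15).
#' @param waveform_seed Integer seed fixing the lobe structure.
#' @return Numeric vector of length `n_samples`.
#' @export
#' @examples
#' k <- make_mep_kernel(2200, 22000, latency_ms = 10, amplitude_uv = 50,
#'                      width_ms = 4, waveform_seed = 7)
#' max(abs(k))
make_mep_kernel <- function(n_samples, fs_hz, latency_ms, amplitude_uv,
                            width_ms, waveform_seed) {
  check_scalar(latency_ms, "latency_ms", positive = TRUE)
  check_scalar(width_ms, "width_ms", positive = TRUE)
  stopifnot(amplitude_uv >= 0)
  t_ms <- epoch_time_ms(n_samples, fs_hz)
  epoch_ms <- n_samples / fs_hz * 1000
  if (latency_ms >= epoch_ms) {
    stop_mep("latency_ms lies outside the epoch", "mep_invalid_kernel")
  }
  if (amplitude_uv == 0) {
    return(numeric(n_samples))
  }
  sigma <- width_ms / (2 * sqrt(2 * log(2)))  # FWHM -> Gaussian sd
  k <- withr::with_seed(waveform_seed, {
    n_side <- sample(1:2, 1)
    main <- exp(-((t_ms - latency_ms)^2) / (2 * sigma^2))
    main_sign <- sample(c(-1, 1), 1)
    out <- main_sign * main
    sides <- sample(c(-1, 1), n_side)       # which side of the main lobe
    if (n_side == 2 && sides[1] == sides[2]) sides[2] <- -sides[2]
    for (s in sides) {
      off <- stats::runif(1, 1.1, 1.35) * width_ms * s
      amp <- -main_sign * stats::runif(1, 0.3, 0.55)
      ssd <- stats::runif(1, 0.45, 0.6) * sigma
      out <- out + amp * exp(-((t_ms - latency_ms - off)^2) / (2 * ssd^2))
    }
    out
  })
  # confine support with a soft shoulder so the hard cut has no step
  lo <- latency_ms - 2 * width_ms
  hi <- latency_ms + 3 * width_ms
  ramp <- 0.35 * width_ms
  w <- rep(0, n_samples)
  core <- t_ms >= lo & t_ms <= hi
  w[core] <- 1
  up <- core & t_ms < lo + ramp
  dn <- core & t_ms > hi - ramp
  w[up] <- 0.5 * (1 - cos(pi * (t_ms[up] - lo) / ramp))
  w[dn] <- 0.5 * (1 - cos(pi * (hi - t_ms[dn]) / ramp))
  k <- k * w
  k * amplitude_uv / max(abs(k))
}

#' Stimulation-artifact description
#'
#' Parameters of the post-pulse amplifier-recovery artifact: an
#' exponentially damped sinusoid that can persist for roughly 20 ms after
#' each pulse, overlapping the short-latency facial response window.
#'
#' @param peak_uv Peak absolute amplitude in microvolts.
#' @param decay_ms Exponential decay time constant, ms.
#' @param osc_freq_hz Oscillation frequency, Hz.
#' @param duration_ms Support of the artifact after the pulse (default 20).
#' @param shared_shape If `TRUE` the same waveform shape (scaled per
#'   channel) is used on every facial channel, which is what makes
#'   cross-channel PCA rejection effective.
#' @return A list with class `"artifact_spec"`.
#' @export
artifact_spec <- function(peak_uv = 25, decay_ms = 5, osc_freq_hz = 180,
                          duration_ms = 20, shared_shape = TRUE) {
  stopifnot(peak_uv >= 0)
  check_scalar(decay_ms, "decay_ms", positive = TRUE)
  check_scalar(osc_freq_hz, "osc_freq_hz", positive = TRUE)
  structure(
    list(peak_uv = peak_uv, decay_ms = decay_ms, osc_freq_hz = osc_freq_hz,
         duration_ms = duration_ms, shared_shape = isTRUE(shared_shape)),
    class = "artifact_spec"
  )
}

# One epoch of the damped-sinusoid artifact, normalized to peak_uv.
artifact_waveform <- function(n_samples, fs_hz, spec) {
  if (spec$peak_uv == 0) return(numeric(n_samples))
  t_ms <- epoch_time_ms(n_samples, fs_hz)
  a <- exp(-t_ms / spec$decay_ms) * sin(2 * pi * spec$osc_freq_hz * t_ms / 1000)
  a[t_ms > spec$duration_ms] <- 0
  a * spec$peak_uv / max(abs(a))
}

#' Per-channel simulation parameters
#'
#' Everything needed to synthesize one EMG channel: the muscle identity, the
#' evoked-response waveform parameters, a threshold-linear recruitment model
#' (no response below `recruitment_threshold_ma`, amplitude growing at
#' `recruitment_gain_uv_per_ma` above it), and the channel's noise budget.
#'
#' @param muscle One-row channel tibble from [muscle_channel()].
#' @param mep_latency_ms Response peak latency, ms; must lie inside the
#'   muscle's detection window when the response amplitude is non-zero.
#' @param mep_amplitude_uv Response amplitude (microvolts) at 1 mA above the
#'   recruitment threshold; also the default recruitment gain.
#' @param mep_width_ms Response width at half maximum, ms (1-15).
#' @param recruitment_threshold_ma Stimulation amplitude below which the
#'   channel does not respond.
#' @param recruitment_gain_uv_per_ma Amplitude slope above threshold;
#'   defaults to `mep_amplitude_uv`.
#' @param amp_override_uv If non-`NULL`, bypasses the recruitment model and
#'   injects a response of exactly this amplitude (used by benchmark corpora
#'   that target specific peak z levels).
#' @param artifact_scale Multiplier on the recording-level artifact for this
#'   channel (0 disables it).
#' @param noise_sd_uv White-noise standard deviation (band-limited to the
#'   amplifier passband), microvolts.
#' @param line_noise_uv 60 Hz line-noise amplitude, microvolts.
#' @param drift_uv Slow (< 2 Hz) baseline-drift standard deviation,
#'   microvolts.
#' @param waveform_seed Integer fixing the response waveform shape.
#' @return A list with class `"sim_channel_spec"`.
#' @export
sim_channel_spec <- function(muscle,
                             mep_latency_ms,
                             mep_amplitude_uv,
                             mep_width_ms = 4,
                             recruitment_threshold_ma = 2,
                             recruitment_gain_uv_per_ma = NULL,
                             amp_override_uv = NULL,
                             artifact_scale = 1,
                             noise_sd_uv = 8,
                             line_noise_uv = 0,
                             drift_uv = 10,
                             waveform_seed = 1) {
  stopifnot(nrow(muscle) == 1L)
  if (is.null(recruitment_gain_uv_per_ma)) {
    recruitment_gain_uv_per_ma <- mep_amplitude_uv
  }
  stopifnot(mep_amplitude_uv >= 0, recruitment_gain_uv_per_ma >= 0,
            artifact_scale >= 0, noise_sd_uv >= 0, line_noise_uv >= 0,
            drift_uv >= 0, mep_width_ms >= 1, mep_width_ms <= 15)
  if (mep_amplitude_uv > 0 || isTRUE(amp_override_uv > 0)) {
    if (mep_latency_ms < muscle$window_low_ms ||
        mep_latency_ms > muscle$window_high_ms) {
      stop_mep(sprintf(
        "mep_latency_ms %.1f outside detection window [%.1f, %.1f] of %s",
        mep_latency_ms, muscle$window_low_ms, muscle$window_high_ms,
        muscle$label), "mep_invalid_sim_spec")
    }
  }
  structure(
    list(muscle = muscle, mep_latency_ms = mep_latency_ms,
         mep_amplitude_uv = mep_amplitude_uv, mep_width_ms = mep_width_ms,
         recruitment_threshold_ma = recruitment_threshold_ma,
         recruitment_gain_uv_per_ma = recruitment_gain_uv_per_ma,
         amp_override_uv = amp_override_uv,
         artifact_scale = artifact_scale, noise_sd_uv = noise_sd_uv,
         line_noise_uv = line_noise_uv, drift_uv = drift_uv,
         waveform_seed = as.integer(waveform_seed)),
    class = "sim_channel_spec"
  )
}

# Effective response amplitude under the recruitment model.
effective_amplitude_uv <- function(spec, amplitude_ma) {
  if (!is.null(spec$amp_override_uv)) {
    return(spec$amp_override_uv)
  }
  spec$recruitment_gain_uv_per_ma *
    max(0, amplitude_ma - spec$recruitment_threshold_ma)
}

# White noise band-limited to the amplifier passband (2nd-order low-pass at
# 3.5 kHz), rescaled to the requested sd.
bandlimited_noise <- function(n, fs_hz, sd_uv, cutoff_hz = 3500) {
  x <- stats::rnorm(n)
  if (cutoff_hz < fs_hz / 2) {
    bf <- signal::butter(2, cutoff_hz / (fs_hz / 2), type = "low")
    x <- signal::filtfilt(bf, x)
  }
  x * sd_uv / stats::sd(x)
}

# Slow baseline drift: random walk generated on a coarse (~100 Hz) grid,
# low-passed below 2 Hz, interpolated to the full rate, rescaled.
slow_drift <- function(n, fs_hz, sd_uv) {
  fs_c <- 100
  m <- max(16L, ceiling(n / fs_hz * fs_c) + 4L)
  w <- cumsum(stats::rnorm(m))
  bf <- signal::butter(2, 2 / (fs_c / 2), type = "low")
  w <- signal::filtfilt(bf, w)
  y <- stats::approx(seq(0, by = 1 / fs_c, length.out = m),
                     w, xout = (seq_len(n) - 1) / fs_hz, rule = 2)$y
  s <- stats::sd(y)
  if (s == 0) numeric(n) else y * sd_uv / s
}

#' Simulate one DBS-EMG recording with ground truth
#'
#' Synthesizes a multi-channel surface-EMG recording for a single
#' stimulation setting: a seeded evoked-response kernel after each pulse on
#' channels recruited at the setting's amplitude, a damped-sinusoid
#' amplifier-recovery artifact after each pulse, 60 Hz line noise with a
#' random (seeded) phase, band-limited white noise, and slow baseline drift.
#' Fully reproducible from `seed`.
#'
#' @param specs List of [sim_channel_spec()], one per channel.
#' @param artifact An [artifact_spec()]; its waveform is scaled per channel
#'   by each spec's `artifact_scale`. When `shared_shape` is `FALSE`, the
#'   oscillation parameters are jittered per channel (seeded).
#' @param setting A [stim_setting()].
#' @param fs_hz Sampling rate in Hz (>= 2000).
#' @param seed Integer seed for all randomness in this recording.
#' @param subject_id,lead_id Identifiers propagated to the recording.
#' @param include_sync If `TRUE`, append a `"stim_sync"` channel carrying
#'   the biphasic stimulus waveform.
#' @return A list with elements `recording` (a [raw_recording()]) and
#'   `annotations` (tibble `setting_id`, `label`, `mep_present` — the ground
#'   truth: `TRUE` iff the channel's effective response amplitude is > 0).
#' @export
simulate_recording <- function(specs, artifact = artifact_spec(peak_uv = 0),
                               setting = stim_setting(3),
                               fs_hz = 22000, seed = 1,
                               subject_id = "S1", lead_id = "L1",
                               include_sync = FALSE) {
  if (fs_hz < 2000) {
    stop_mep("fs_hz must be >= 2000", "mep_invalid_argument")
  }
  n <- round(fs_hz * setting$duration_s)
  epoch_len <- round(fs_hz / setting$frequency_hz)
  onsets <- seq.int(1L, by = epoch_len, length.out = floor(n / epoch_len))
  n_ch <- length(specs)
  channels <- dplyr::bind_rows(lapply(specs, function(s) s$muscle))

  t_s <- (seq_len(n) - 1) / fs_hz
  base_art <- artifact_waveform(epoch_len, fs_hz, artifact)

  sig <- withr::with_seed(as.integer(seed), {
    line_phase <- stats::runif(1, 0, 2 * pi)
    m <- matrix(0, nrow = n_ch, ncol = n)
    for (ci in seq_len(n_ch)) {
      sp <- specs[[ci]]
      x <- numeric(n)
      amp_eff <- effective_amplitude_uv(sp, setting$amplitude_ma)
      pulse_add <- numeric(epoch_len)
      if (amp_eff > 0) {
        pulse_add <- pulse_add +
          make_mep_kernel(epoch_len, fs_hz, sp$mep_latency_ms, amp_eff,
                          sp$mep_width_ms, sp$waveform_seed)
      }
      if (sp$artifact_scale > 0 && artifact$peak_uv > 0) {
        art <- base_art
        if (!artifact$shared_shape) {
          jit <- artifact_spec(
            peak_uv = artifact$peak_uv,
            decay_ms = artifact$decay_ms * stats::runif(1, 0.9, 1.1),
            osc_freq_hz = artifact$osc_freq_hz * stats::runif(1, 0.9, 1.1),
            duration_ms = artifact$duration_ms,
            shared_shape = FALSE
          )
          art <- artifact_waveform(epoch_len, fs_hz, jit)
        }
        pulse_add <- pulse_add + sp$artifact_scale * art
      }
      if (any(pulse_add != 0)) {
        for (o in onsets) {
          idx <- o:(min(n, o + epoch_len - 1L))
          x[idx] <- x[idx] + pulse_add[seq_along(idx)]
        }
      }
      if (sp$noise_sd_uv > 0) {
        x <- x + bandlimited_noise(n, fs_hz, sp$noise_sd_uv)
      }
      if (sp$line_noise_uv > 0) {
        x <- x + sp$line_noise_uv * sin(2 * pi * 60 * t_s + line_phase)
      }
      if (sp$drift_uv > 0) {
        x <- x + slow_drift(n, fs_hz, sp$drift_uv)
      }
      m[ci, ] <- x
    }
    m
  })

  if (include_sync) {
    pw <- stim_pulse_waveform(setting, fs_hz) * setting$amplitude_ma * 1000
    sync <- numeric(n)
    for (o in onsets) {
      idx <- o:min(n, o + length(pw) - 1L)
      sync[idx] <- sync[idx] + pw[seq_along(idx)]
    }
    sig <- rbind(sig, sync)
    channels <- dplyr::bind_rows(
      channels,
      tibble::tibble(label = "stim_sync", group = "limb", laterality = "CL",
                     window_low_ms = 10, window_high_ms = 40)
    )
  }

  rec <- raw_recording(sig, fs_hz, onsets, channels, setting,
                       subject_id = subject_id, lead_id = lead_id)
  ann <- tibble::tibble(
    setting_id = setting$setting_id,
    label = vapply(specs, function(s) s$muscle$label, character(1)),
    mep_present = vapply(
      specs,
      function(s) effective_amplitude_uv(s, setting$amplitude_ma) > 0,
      logical(1)
    )
  )
  list(recording = rec, annotations = ann)
}
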