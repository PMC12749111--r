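#' Plan a synthetic multi-subject corpus
#'
#' Lays out a reproducible corpus of simulated recordings emulating an
#' intraoperative study: each subject (DBS lead) keeps fixed per-muscle
#' response waveforms (latency, shape, width) across stimulation settings —
#' the within-subject stereotypy of real evoked responses — while settings
#' vary in amplitude and contact. The plan is a tibble; recordings are
#' realized one at a time with [realize_recording()] so arbitrarily large
#' corpora never need to be held in memory.
#'
#' Recruitment is threshold-like and steep: a channel responds only above
#' its per-subject threshold amplitude, and when it responds its
#' pulse-averaged peak starts at `response_jump_z` times the group detection
#' threshold (in baseline z units) and grows by `response_gain_z_per_ma` per
#' mA above threshold. Line interference is placed predominantly on limb
#' channels and the recovery artifact on facial channels, the two failure
#' modes the detector's filtering stages target.
#'
#' When `z_factors` is supplied (e.g. `c(0, 1.5, 3)`), recruitment is
#' replaced by direct injection: each channel/setting draws one factor and
#' the response amplitude is set to `factor * group_threshold` baseline
#' z units exactly, giving a stress corpus with known detection margins.
#'
#' @param n_subjects,settings_per_subject Corpus dimensions (>= 1).
#' @param seed Integer; all draws derive from it.
#' @param muscles Character vector of canonical muscle labels to record.
#' @param fs_hz,frequency_hz,duration_s Acquisition parameters.
#' @param amplitude_range_ma Settings draw amplitudes uniformly on this
#'   range (rounded to 0.5 mA).
#' @param recruitment_range_ma Per-subject, per-muscle response thresholds
#'   are drawn uniformly on this range.
#' @param response_jump_z,response_gain_z_per_ma Steep recruitment model
#'   (see Details), in units of the group detection threshold and of
#'   baseline z per mA.
#' @param z_factors Optional numeric vector switching to direct z-targeted
#'   injection (0 = no response).
#' @param noise_sd_uv,line_noise_limb_uv,line_noise_facial_uv,drift_uv
#'   Channel noise budget, microvolts.
#' @param artifact_peak_range_uv,artifact_decay_range_ms,artifact_freq_range_hz
#'   Per-subject artifact family; per-setting realizations jitter the decay
#'   and frequency by about 5% and scale the peak with stimulation
#'   amplitude.
#' @param artifact_scale_facial,artifact_scale_limb Group-level artifact
#'   multipliers.
#' @param thresholds A [detection_config()] supplying the group thresholds
#'   used to express response amplitudes in z units.
#' @return A tibble with one row per (subject, setting): identifiers,
#'   stimulation parameters, a seeded `rec_seed`, and list-columns
#'   `channel_specs` / `artifact`.
#' @seealso [realize_recording()], [simulate_corpus()]
#' @export
corpus_plan <- function(n_subjects, settings_per_subject, seed = 1,
                        muscles = c("CL_nasalis", "CL_orb_oris", "IL_nasalis",
                                    "CL_ECR", "CL_FCR", "CL_FDI"),
                        fs_hz = 22000, frequency_hz = 10, duration_s = 12,
                        amplitude_range_ma = c(1, 5),
                        recruitment_range_ma = c(1.5, 4),
                        response_jump_z = 2,
                        response_gain_z_per_ma = 12,
                        z_factors = NULL,
                        noise_sd_uv = 8,
                        line_noise_limb_uv = 4,
                        line_noise_facial_uv = 0.4,
                        drift_uv = 10,
                        artifact_peak_range_uv = c(10, 40),
                        artifact_decay_range_ms = c(3, 7),
                        artifact_freq_range_hz = c(100, 250),
                        artifact_scale_facial = 1,
                        artifact_scale_limb = 0.3,
                        thresholds = detection_config()) {
  stopifnot(n_subjects >= 1, settings_per_subject >= 1)
  seed <- as.integer(seed)
  muscle_tbl <- dplyr::bind_rows(lapply(muscles, muscle_channel))
  epoch_len <- round(fs_hz / frequency_hz)
  n_pulses <- floor(round(fs_hz * duration_s) / epoch_len)
  z_unit_uv <- noise_sd_uv / sqrt(n_pulses)   # baseline sd of the average
  contacts <- c("1", "2", "3", "4", "2A", "2M", "2L", "3A", "3M", "3L")

  withr::with_seed(seed, {
    rows <- vector("list", n_subjects * settings_per_subject)
    ri <- 0L
    for (s in seq_len(n_subjects)) {
      subject_id <- sprintf("S%02d", s)
      # subject-level physiology: fixed waveforms and thresholds
      subj <- lapply(seq_len(nrow(muscle_tbl)), function(m) {
        mu <- muscle_tbl[m, ]
        span <- mu$window_high_ms - mu$window_low_ms
        list(
          muscle = mu,
          latency = stats::runif(1, mu$window_low_ms + 0.2 * span,
                                 mu$window_high_ms - 0.25 * span),
          width = if (mu$group == "facial") stats::runif(1, 2, 5)
                  else stats::runif(1, 3, 8),
          thr_ma = stats::runif(1, recruitment_range_ma[1],
                                recruitment_range_ma[2]),
          waveform_seed = (seed * 1009L + s * 131L + m) %%
            .Machine$integer.max
        )
      })
      art_base <- list(
        peak = stats::runif(1, artifact_peak_range_uv[1],
                            artifact_peak_range_uv[2]),
        decay = stats::runif(1, artifact_decay_range_ms[1],
                             artifact_decay_range_ms[2]),
        freq = stats::runif(1, artifact_freq_range_hz[1],
                            artifact_freq_range_hz[2])
      )
      ch_scale <- stats::rlnorm(nrow(muscle_tbl), 0, 0.2)

      for (k in seq_len(settings_per_subject)) {
        ri <- ri + 1L
        amplitude_ma <- round(stats::runif(1, amplitude_range_ma[1],
                                           amplitude_range_ma[2]) * 2) / 2
        contact <- sample(contacts, 1)
        specs <- vector("list", nrow(muscle_tbl))
        for (m in seq_len(nrow(muscle_tbl))) {
          p <- subj[[m]]
          grp_thr <- group_threshold(p$muscle$group, thresholds)
          if (is.null(z_factors)) {
            excess <- amplitude_ma - p$thr_ma
            override <- if (excess > 0) {
              (response_jump_z * grp_thr +
                 response_gain_z_per_ma * excess) * z_unit_uv
            } else 0
          } else {
            f <- sample(z_factors, 1)
            override <- f * grp_thr * z_unit_uv
          }
          specs[[m]] <- sim_channel_spec(
            muscle = p$muscle,
            mep_latency_ms = p$latency,
            mep_amplitude_uv = override,
            mep_width_ms = p$width,
            recruitment_threshold_ma = p$thr_ma,
            amp_override_uv = override,
            artifact_scale = ch_scale[m] *
              (if (p$muscle$group == "facial") artifact_scale_facial
               else artifact_scale_limb),
            noise_sd_uv = noise_sd_uv,
            line_noise_uv = if (p$muscle$group == "facial")
              line_noise_facial_uv else line_noise_limb_uv,
            drift_uv = drift_uv,
            waveform_seed = p$waveform_seed
          )
        }
        art <- artifact_spec(
          peak_uv = art_base$peak * amplitude_ma / 3,
          decay_ms = art_base$decay * stats::runif(1, 0.95, 1.05),
          osc_freq_hz = art_base$freq * stats::runif(1, 0.95, 1.05),
          shared_shape = TRUE
        )
        rows[[ri]] <- tibble::tibble(
          subject_id = subject_id,
          lead_id = paste0(subject_id, "_L"),
          setting_index = k,
          setting_id = sprintf("%s_set%02d", subject_id, k),
          amplitude_ma = amplitude_ma,
          pulse_width_us = 60,
          frequency_hz = frequency_hz,
          duration_s = duration_s,
          fs_hz = fs_hz,
          contact_config = contact,
          rec_seed = (seed * 7919L + ri) %% .Machine$integer.max,
          channel_specs = list(specs),
          artifact = list(art)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Realize one planned recording
#'
#' Deterministically generates the `i`-th recording of a [corpus_plan()].
#'
#' @param plan Tibble from [corpus_plan()].
#' @param i Row index.
#' @return As [simulate_recording()]: `list(recording, annotations)`, with
#'   the annotations carrying the subject id.
#' @export
realize_recording <- function(plan, i) {
  row <- plan[i, ]
  setting <- stim_setting(
    amplitude_ma = row$amplitude_ma,
    pulse_width_us = row$pulse_width_us,
    frequency_hz = row$frequency_hz,
    duration_s = row$duration_s,
    contact_config = row$contact_config,
    setting_id = row$setting_id
  )
  out <- simulate_recording(
    specs = row$channel_specs[[1]],
    artifact = row$artifact[[1]],
    setting = setting,
    fs_hz = row$fs_hz,
    seed = row$rec_seed,
    subject_id = row$subject_id,
    lead_id = row$lead_id
  )
  out$annotations$subject_id <- row$subject_id
  out
}

#' Simulate a full corpus in memory
#'
#' Convenience wrapper realizing every row of a [corpus_plan()]. Use only
#' for small corpora; large benchmark corpora should be streamed row by row
#' with [realize_recording()].
#'
#' @inheritParams corpus_plan
#' @param ... Passed to [corpus_plan()].
#' @return List of `list(recording, annotations)`.
#' @export
simulate_corpus <- function(n_subjects, settings_per_subject, seed = 1, ...) {
  plan <- corpus_plan(n_subjects, settings_per_subject, seed = seed, ...)
  lapply(seq_len(nrow(plan)), function(i) realize_recording(plan, i))
}

#' Generate pure-artifact traces for template-library construction
#'
#' Simulates single facial-channel recordings containing stimulation
#' artifact and noise but no evoked response (the synthetic stand-in for the
#' annotated artifact-only settings a template library is built from), and
#' returns their pulse-triggered averages.
#'
#' @param n Number of traces (the reference library uses 192).
#' @param seed Integer seed.
#' @param fs_hz,frequency_hz,duration_s Acquisition parameters.
#' @param artifact_peak_range_uv,artifact_decay_range_ms,artifact_freq_range_hz
#'   Artifact family sampled per trace; defaults match [corpus_plan()].
#' @param noise_sd_uv,line_noise_uv,drift_uv Channel noise budget.
#' @return A traces tibble (see [epoch_average()]) with `n` rows.
#' @export
simulate_pure_artifact_traces <- function(n = 192, seed = 1,
                                          fs_hz = 22000, frequency_hz = 10,
                                          duration_s = 12,
                                          artifact_peak_range_uv = c(10, 40),
                                          artifact_decay_range_ms = c(3, 7),
                                          artifact_freq_range_hz = c(100, 250),
                                          noise_sd_uv = 8,
                                          line_noise_uv = 0.4,
                                          drift_uv = 10) {
  stopifnot(n >= 1)
  seed <- as.integer(seed)
  pars <- withr::with_seed(seed, tibble::tibble(
    peak = stats::runif(n, artifact_peak_range_uv[1], artifact_peak_range_uv[2]),
    decay = stats::runif(n, artifact_decay_range_ms[1], artifact_decay_range_ms[2]),
    freq = stats::runif(n, artifact_freq_range_hz[1], artifact_freq_range_hz[2])
  ))
  mu <- muscle_channel("CL_nasalis")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- sim_channel_spec(
      muscle = mu, mep_latency_ms = 10, mep_amplitude_uv = 0,
      artifact_scale = 1, noise_sd_uv = noise_sd_uv,
      line_noise_uv = line_noise_uv, drift_uv = drift_uv,
      waveform_seed = 1
    )
    art <- artifact_spec(peak_uv = pars$peak[i], decay_ms = pars$decay[i],
                         osc_freq_hz = pars$freq[i])
    sim <- simulate_recording(
      list(sp), art,
      setting = stim_setting(3, frequency_hz = frequency_hz,
                             duration_s = duration_s,
                             setting_id = sprintf("art%03d", i)),
      fs_hz = fs_hz, seed = (seed * 613L + i) %% .Machine$integer.max,
      subject_id = sprintf("A%03d", i)
    )
    tr <- epoch_average(sim$recording)
    tr$setting_id <- sprintf("art%03d", i)
    out[[i]] <- tr
  }
  dplyr::bind_rows(out)
}
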