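# Fixtures built in code. Everything here is deterministic (explicit seeds).

FS <- 22000

# Construct an averaged_trace directly from a numeric vector.
toy_trace <- function(values, fs_hz = FS, label = "CL_nasalis",
                      n_pulses = 120, frequency_hz = 10) {
  structure(
    list(values = values, fs_hz = fs_hz, frequency_hz = frequency_hz,
         n_pulses = n_pulses, channel = muscle_channel(label)),
    class = "averaged_trace"
  )
}

toy_ztrace <- function(values, fs_hz = FS, label = "CL_nasalis",
                       baseline_sd_uv = 1, baseline_median_uv = 0) {
  structure(
    list(values = values, baseline_median_uv = baseline_median_uv,
         baseline_sd_uv = baseline_sd_uv, fs_hz = fs_hz, frequency_hz = 10,
         n_pulses = 120, channel = muscle_channel(label)),
    class = "zscored_trace"
  )
}

epoch_ms_axis <- function(n, fs_hz = FS) (seq_len(n) - 1) / fs_hz * 1000

# A smooth unit-peak Gaussian bump at a given latency/width (ms).
gauss_bump <- function(n, latency_ms, width_ms, fs_hz = FS) {
  t <- epoch_ms_axis(n, fs_hz)
  s <- width_ms / (2 * sqrt(2 * log(2)))
  exp(-((t - latency_ms)^2) / (2 * s^2))
}

# One damped-sinusoid artifact epoch.
toy_artifact <- function(n, peak_uv = 25, decay_ms = 5, freq_hz = 180,
                         fs_hz = FS) {
  t <- epoch_ms_axis(n, fs_hz)
  a <- exp(-t / decay_ms) * sin(2 * pi * freq_hz * t / 1000)
  a[t > 20] <- 0
  a * peak_uv / max(abs(a))
}

# Cheap pure-artifact traces (epoch-level construction; for the unit tests —
# the acceptance suite builds its library from full simulated recordings).
toy_artifact_traces <- function(n_traces, seed = 1, n = 2200, fs_hz = FS) {
  withr::with_seed(seed, {
    lapply(seq_len(n_traces), function(i) {
      toy_trace(
        toy_artifact(n, peak_uv = runif(1, 10, 40),
                     decay_ms = runif(1, 3, 7),
                     freq_hz = runif(1, 100, 250), fs_hz = fs_hz) +
          rnorm(n, sd = 0.7),
        fs_hz = fs_hz
      )
    })
  })
}

# Small high-SNR two-channel recording (one facial responder, one limb
# non-responder), short duration to keep unit tests fast.
quick_sim <- function(seed = 3, duration_s = 2, amplitude_ma = 3.5,
                      mep_amplitude_uv = 40, artifact_peak = 0,
                      noise_sd = 6) {
  specs <- list(
    sim_channel_spec(muscle_channel("CL_nasalis"), mep_latency_ms = 10,
                     mep_amplitude_uv = mep_amplitude_uv,
                     recruitment_threshold_ma = 2,
                     noise_sd_uv = noise_sd, drift_uv = 3, waveform_seed = 11),
    sim_channel_spec(muscle_channel("CL_ECR"), mep_latency_ms = 22,
                     mep_amplitude_uv = 0, recruitment_threshold_ma = 10,
                     noise_sd_uv = noise_sd, drift_uv = 3, waveform_seed = 12)
  )
  simulate_recording(
    specs, artifact_spec(peak_uv = artifact_peak),
    setting = stim_setting(amplitude_ma, duration_s = duration_s),
    seed = seed
  )
}

# Session-level cache for expensive shared fixtures (built on first use).
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, build(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# The reference template library: 192 pure-artifact simulated recordings.
reference_library <- function() {
  cached_fixture("reference_library", function() {
    build_template_library(simulate_pure_artifact_traces(n = 192, seed = 421))
  })
}
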