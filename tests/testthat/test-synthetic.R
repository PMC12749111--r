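# Synthetic EMG generator: kernel geometry, determinism, recruitment,
# annotation consistency, linearity.

test_that("kernel peak location, height and width match the request", {
  k <- make_mep_kernel(2200, FS, latency_ms = 10, amplitude_uv = 50,
                       width_ms = 4, waveform_seed = 7)
  t_ms <- epoch_ms_axis(2200)
  expect_equal(max(abs(k)), 50)
  expect_lt(abs(t_ms[which.max(abs(k))] - 10), 0.25)
  # FWHM of the dominant lobe within 10%
  r <- abs(k); p <- which.max(r); h <- r[p] / 2
  l <- p; while (r[l] > h) l <- l - 1
  u <- p; while (r[u] > h) u <- u + 1
  fwhm <- (u - l) / FS * 1000
  expect_lt(abs(fwhm - 4) / 4, 0.10)
})

test_that("kernel support is confined to [latency - 2w, latency + 3w]", {
  for (seed in 1:5) {
    k <- make_mep_kernel(2200, FS, 12, 30, 3, seed)
    t_ms <- epoch_ms_axis(2200)
    expect_true(all(k[t_ms < 12 - 2 * 3 | t_ms > 12 + 3 * 3] == 0))
  }
})

test_that("kernel is deterministic per seed and zero at zero amplitude", {
  expect_identical(
    make_mep_kernel(2200, FS, 10, 50, 4, 3),
    make_mep_kernel(2200, FS, 10, 50, 4, 3)
  )
  expect_false(isTRUE(all.equal(
    make_mep_kernel(2200, FS, 10, 50, 4, 3),
    make_mep_kernel(2200, FS, 10, 50, 4, 4)
  )))
  expect_identical(make_mep_kernel(2200, FS, 10, 0, 4, 3), numeric(2200))
  expect_error(make_mep_kernel(2200, FS, 150, 10, 4, 3),
               class = "mep_invalid_kernel")
})

test_that("default train geometry gives 120 onsets spaced 2200 samples", {
  sim <- simulate_recording(
    list(sim_channel_spec(muscle_channel("CL_nasalis"), 10, 0,
                          noise_sd_uv = 0, drift_uv = 0)),
    seed = 1
  )
  on <- sim$recording$pulse_onsets
  expect_length(on, 120)
  expect_true(all(diff(on) == 2200))
})

test_that("all-zero noise/artifact/response gives an all-zero signal", {
  sim <- simulate_recording(
    list(sim_channel_spec(muscle_channel("CL_nasalis"), 10, 0,
                          noise_sd_uv = 0, line_noise_uv = 0, drift_uv = 0)),
    artifact_spec(peak_uv = 0), seed = 1
  )
  expect_true(all(sim$recording$signal == 0))
  expect_false(any(sim$annotations$mep_present))
})

test_that("stimulation below every recruitment threshold annotates false", {
  specs <- list(
    sim_channel_spec(muscle_channel("CL_nasalis"), 10, 50,
                     recruitment_threshold_ma = 3, noise_sd_uv = 1),
    sim_channel_spec(muscle_channel("CL_ECR"), 22, 50,
                     recruitment_threshold_ma = 4, noise_sd_uv = 1)
  )
  sim <- simulate_recording(specs, setting = stim_setting(2, duration_s = 1),
                            seed = 2)
  expect_false(any(sim$annotations$mep_present))
})

test_that("identical seeds reproduce the recording exactly", {
  a <- quick_sim(seed = 9, duration_s = 1)
  b <- quick_sim(seed = 9, duration_s = 1)
  expect_identical(a$recording$signal, b$recording$signal)
  c <- quick_sim(seed = 10, duration_s = 1)
  expect_false(identical(a$recording$signal, c$recording$signal))
})

test_that("annotations are consistent with injected kernels", {
  sim <- quick_sim(seed = 5, duration_s = 1)
  ann <- sim$annotations
  expect_true(ann$mep_present[ann$label == "CL_nasalis"])
  expect_false(ann$mep_present[ann$label == "CL_ECR"])
})

test_that("response amplitude is linear in mep_amplitude_uv (zero noise)", {
  mk <- function(amp) {
    sim <- simulate_recording(
      list(sim_channel_spec(muscle_channel("CL_nasalis"), 10, amp,
                            recruitment_threshold_ma = 2,
                            noise_sd_uv = 0, line_noise_uv = 0, drift_uv = 0,
                            waveform_seed = 5)),
      setting = stim_setting(3, duration_s = 1), seed = 1
    )
    tr <- epoch_average(sim$recording)
    max(abs(tr$trace[[1]]$values))
  }
  expect_equal(mk(40), 2 * mk(20), tolerance = 1e-10)
})

test_that("corpus plans are deterministic and sized correctly", {
  p1 <- corpus_plan(2, 3, seed = 7, duration_s = 2)
  p2 <- corpus_plan(2, 3, seed = 7, duration_s = 2)
  expect_equal(nrow(p1), 6L)
  expect_identical(p1$rec_seed, p2$rec_seed)
  r1 <- realize_recording(p1, 4)
  r2 <- realize_recording(p2, 4)
  expect_identical(r1$recording$signal, r2$recording$signal)
  corpus <- simulate_corpus(1, 2, seed = 3, duration_s = 1)
  expect_length(corpus, 2L)
})

test_that("z-factor corpora inject amplitudes at the targeted z levels", {
  plan <- corpus_plan(1, 4, seed = 21, z_factors = c(0, 1.5, 3),
                      duration_s = 2)
  z_unit <- 8 / sqrt(floor(2 * 22000 / 2200))   # noise_sd / sqrt(n_pulses)
  for (specs in plan$channel_specs) {
    for (sp in specs) {
      thr <- if (sp$muscle$group == "facial") 4 else 7
      f <- sp$amp_override_uv / (thr * z_unit)
      expect_true(any(abs(f - c(0, 1.5, 3)) < 1e-9))
    }
  }
})
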