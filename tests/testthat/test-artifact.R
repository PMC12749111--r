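# Template library construction and the three artifact-rejection methods.

test_that("library augmentation pairs every template with its negation", {
  lib <- build_template_library(toy_artifact_traces(6, seed = 1))
  expect_equal(nrow(lib$templates), 12L)
  expect_equal(lib$templates[7:12, ], -lib$templates[1:6, ])
  lib1 <- build_template_library(toy_artifact_traces(1, seed = 2))
  expect_equal(nrow(lib1$templates), 2L)
  expect_equal(lib1$templates[2, ], -lib1$templates[1, ])
})

test_that("Savitzky-Golay smoothing strips high-frequency power", {
  withr::with_seed(4, tr <- toy_trace(rnorm(2200)))
  lib <- build_template_library(list(tr))
  # spectral oracle: compare >2 kHz power of template vs raw input window
  win <- which(epoch_ms_axis(2200) >= 2 & epoch_ms_axis(2200) <= 20)
  hf_power <- function(x) {
    s <- abs(fft(x - mean(x)))^2
    f <- (seq_along(x) - 1) / length(x) * FS
    sum(s[f > 2000 & f < FS - 2000])
  }
  expect_lt(hf_power(lib$templates[1, ]) / hf_power(tr$values[win]), 0.10)
})

test_that("library round-trips through CSV + JSON", {
  lib <- build_template_library(toy_artifact_traces(3, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_template_library(lib, path)
  back <- read_template_library(path)
  expect_equal(back$templates, lib$templates, tolerance = 1e-12)
  expect_equal(back$window_ms, lib$window_ms)
  expect_equal(back$fs_hz, lib$fs_hz)
})

test_that("template rejection suppresses a known library artifact", {
  lib <- build_template_library(toy_artifact_traces(12, seed = 6))
  withr::with_seed(7, noise <- rnorm(2200, sd = 0.5))
  win <- window_idx(2200, FS, c(2, 20))
  v <- noise
  v[win] <- v[win] + 2.5 * lib$templates[3, ]
  out <- template_reject(toy_trace(v), lib)
  z <- baseline_zscore(out)
  zwin <- epoch_ms_axis(2200) >= 5 & epoch_ms_axis(2200) <= 18
  expect_lt(max(abs(z$values[zwin])), 4)
  expect_equal(attr(out, "template_index"), 3L)
  expect_equal(attr(out, "template_scale"), 2.5, tolerance = 0.1)
})

test_that("template rejection leaves an all-zero trace unchanged", {
  lib <- build_template_library(toy_artifact_traces(2, seed = 8))
  out <- template_reject(toy_trace(numeric(2200)), lib)
  expect_true(all(out$values == 0))
  expect_equal(attr(out, "template_scale"), 0)
})

test_that("an evoked bump survives template rejection and stays detected", {
  lib <- build_template_library(toy_artifact_traces(12, seed = 9))
  withr::with_seed(10, noise <- rnorm(2200, sd = 0.7))
  win <- window_idx(2200, FS, c(2, 20))
  bump <- 40 * gauss_bump(2200, 9, 3.5)
  v <- noise + bump
  v[win] <- v[win] + 1.8 * lib$templates[5, ]
  out <- template_reject(toy_trace(v), lib)
  pk <- which.max(bump)
  expect_lt(abs(out$values[pk] - bump[pk]) / bump[pk], 0.25)
  det <- detect_mep(baseline_zscore(out))
  expect_identical(det$status, "response")
  expect_lt(abs(det$latency_ms - 9), 1.5)
})

test_that("rejection modifies the trace only inside the 2-20 ms window", {
  lib <- build_template_library(toy_artifact_traces(4, seed = 11))
  withr::with_seed(12, v <- rnorm(2200) + toy_artifact(2200, peak_uv = 15))
  win <- window_idx(2200, FS, c(2, 20))
  out_t <- template_reject(toy_trace(v), lib)
  expect_identical(out_t$values[-win], v[-win])
  traces <- tibble::tibble(
    subject_id = "S1", setting_id = "s", label = c("CL_nasalis", "IL_nasalis"),
    group = "facial", laterality = c("CL", "IL"),
    trace = list(toy_trace(v), toy_trace(v * 1.2, label = "IL_nasalis"))
  )
  out_p <- pca_reject(traces)
  expect_identical(out_p$trace[[1]]$values[-win], v[-win])
  out_h <- template_pca_reject(traces, lib)
  expect_identical(out_h$trace[[1]]$values[-win], v[-win])
})

test_that("matched-template subtraction approximately removes added scale", {
  lib <- build_template_library(toy_artifact_traces(10, seed = 13))
  withr::with_seed(14, base <- rnorm(2200, sd = 0.3))
  win <- window_idx(2200, FS, c(2, 20))
  tmpl <- lib$templates[2, ]
  c_scale <- 6
  with_art <- base
  with_art[win] <- with_art[win] + c_scale * tmpl
  r1 <- template_reject(toy_trace(with_art), lib)
  r0 <- template_reject(toy_trace(base), lib)
  diff_rms <- sqrt(mean((r1$values[win] - r0$values[win])^2))
  expect_lt(diff_rms, 0.10 * c_scale * sqrt(mean(tmpl^2)))
})

# Six facial channels sharing one artifact waveform at channel-specific
# scales (the full bilateral facial montage); optionally one channel also
# carries an evoked bump. With few channels a single-channel bump would
# dominate PC1 and void the premise of cross-channel artifact estimation.
facial_traces_with_shared_artifact <- function(bump_channel = NULL,
                                               bump_uv = 0, seed = 20,
                                               art_scales = c(1, 1.2, 0.9,
                                                              1.1, 0.8, 1.05),
                                               noise_sd = 0.3,
                                               art_peak = 40) {
  labs <- c("CL_nasalis", "IL_nasalis", "CL_orb_oris", "IL_orb_oris",
            "CL_genioglossus", "IL_genioglossus")
  art <- toy_artifact(2200, peak_uv = art_peak, decay_ms = 5, freq_hz = 160)
  withr::with_seed(seed, {
    traces <- lapply(seq_along(labs), function(i) {
      v <- art_scales[i] * art + rnorm(2200, sd = noise_sd)
      if (!is.null(bump_channel) && i == bump_channel) {
        v <- v + bump_uv * gauss_bump(2200, 11, 3)
      }
      toy_trace(v, label = labs[i])
    })
  })
  tibble::tibble(
    subject_id = "S1", setting_id = "s", label = labs, group = "facial",
    laterality = substr(labs, 1, 2), trace = traces
  )
}

test_that("PCA rejection removes an artifact shared across channels", {
  # identical waveform on every channel, near-noiseless: PC1 is the artifact
  traces <- facial_traces_with_shared_artifact(art_scales = rep(1, 6),
                                               noise_sd = 0.02)
  win <- window_idx(2200, FS, c(2, 20))
  before <- sqrt(mean(traces$trace[[1]]$values[win]^2))
  out <- pca_reject(traces)
  after <- sqrt(mean(out$trace[[1]]$values[win]^2))
  expect_lt(after / before, 0.05)
})

test_that("PCA rejection with median-scaling preserves an uncorrelated bump", {
  traces <- facial_traces_with_shared_artifact(bump_channel = 1, bump_uv = 15)
  out <- pca_reject(traces, scaling = "median_scaling")
  bump <- 15 * gauss_bump(2200, 11, 3)
  pk <- which.max(bump)
  expect_lt(abs(out$trace[[1]]$values[pk] - bump[pk]) / bump[pk], 0.25)
})

test_that("remove_pc1 distorts a large evoked bump more than median-scaling", {
  traces <- facial_traces_with_shared_artifact(bump_channel = 1, bump_uv = 15)
  bump <- 15 * gauss_bump(2200, 11, 3)
  pk <- which.max(bump)
  err <- function(out) abs(out$trace[[1]]$values[pk] - bump[pk])
  e_med <- err(pca_reject(traces, scaling = "median_scaling"))
  e_pc1 <- err(pca_reject(traces, scaling = "remove_pc1"))
  expect_gt(e_pc1, e_med)
})

test_that("PCA rejection warns and passes through with a lone channel", {
  traces <- facial_traces_with_shared_artifact()[1, ]
  expect_warning(out <- pca_reject(traces), "fewer than 2")
  expect_identical(out$trace[[1]]$values, traces$trace[[1]]$values)
})

test_that("template-PCA beats plain PCA when the library holds the shape", {
  # heterogeneous artifact scales across channels strain plain PC1 fitting;
  # anchoring with the exact library shape must not do worse
  traces <- facial_traces_with_shared_artifact(
    art_scales = c(1, 3, 0.3, 1.5, 0.6, 2))
  art_tr <- toy_trace(toy_artifact(2200, peak_uv = 25, decay_ms = 5,
                                   freq_hz = 160))
  lib <- build_template_library(list(art_tr))
  win <- window_idx(2200, FS, c(2, 20))
  rms <- function(out) sqrt(mean(out$trace[[1]]$values[win]^2))
  r_pca <- rms(pca_reject(traces))
  r_hyb <- rms(template_pca_reject(traces, lib))
  expect_lt(r_hyb, r_pca * 1.05)
})

test_that("template-PCA runs with a single facial channel", {
  traces <- facial_traces_with_shared_artifact()[1, ]
  lib <- build_template_library(toy_artifact_traces(4, seed = 22))
  out <- template_pca_reject(traces, lib)
  expect_s3_class(out$trace[[1]], "averaged_trace")
  expect_equal(nrow(out), 1L)
})

test_that("template rejection does not hurt aggregate detection accuracy", {
  # facial traces with artifact on; half carry a detectable bump
  lib <- build_template_library(toy_artifact_traces(24, seed = 30))
  outcomes <- withr::with_seed(31, {
    sapply(1:16, function(i) {
      has_bump <- i %% 2 == 0
      v <- toy_artifact(2200, peak_uv = runif(1, 10, 30),
                        decay_ms = runif(1, 3, 7),
                        freq_hz = runif(1, 100, 250)) + rnorm(2200, sd = 0.7)
      if (has_bump) v <- v + 8 * gauss_bump(2200, 10, 3.5)
      tr <- toy_trace(v)
      naive <- detect_mep(baseline_zscore(tr))$status == "response"
      rej <- detect_mep(baseline_zscore(template_reject(tr, lib)))$status ==
        "response"
      c(truth = has_bump, naive = naive, rej = rej)
    })
  })
  acc_naive <- mean(outcomes["naive", ] == outcomes["truth", ])
  acc_rej <- mean(outcomes["rej", ] == outcomes["truth", ])
  expect_gte(acc_rej, acc_naive)
})
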