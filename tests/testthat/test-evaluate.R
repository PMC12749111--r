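# Accuracy, F1 sweeps, waveform correlation, duration sweep, summaries.

toy_results <- function() {
  det <- tidyr::expand_grid(
    setting_id = sprintf("s%d", 1:5),
    label = c("CL_nasalis", "CL_ECR")
  )
  det$status <- "no_response"
  det$status[det$setting_id %in% c("s1", "s2") &
               det$label == "CL_nasalis"] <- "response"
  ann <- det[, c("setting_id", "label")]
  ann$mep_present <- det$status == "response"
  list(det = det, ann = ann)
}

test_that("accuracy is 1 on perfect and 0 on inverted predictions", {
  r <- toy_results()
  acc <- detection_accuracy(r$det, r$ann)
  expect_true(all(acc$per_muscle$accuracy == 1))
  expect_equal(acc$median_accuracy, 1)
  flipped <- r$ann
  flipped$mep_present <- !flipped$mep_present
  acc0 <- detection_accuracy(r$det, flipped)
  expect_true(all(acc0$per_muscle$accuracy == 0))
})

test_that("accuracy counts match a constructed confusion table", {
  # one muscle, 10 settings: 3 TP, 1 FP, 5 TN, 1 FN -> accuracy 0.8
  det <- tibble::tibble(
    setting_id = sprintf("s%d", 1:10), label = "CL_ECR",
    status = c(rep("response", 4), rep("no_response", 6))
  )
  ann <- tibble::tibble(
    setting_id = sprintf("s%d", 1:10), label = "CL_ECR",
    mep_present = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                    FALSE, TRUE)
  )
  acc <- detection_accuracy(det, ann)
  expect_equal(acc$per_muscle$accuracy, 0.8)
})

test_that("excluded channels drop out of the accuracy denominator", {
  r <- toy_results()
  det <- r$det
  det$status[det$setting_id == "s5"] <- "excluded"
  acc <- detection_accuracy(det, r$ann)
  expect_equal(acc$per_muscle$n, c(4L, 4L))
  expect_error(detection_accuracy(det[0, ], r$ann),
               class = "mep_empty_overlap")
})

test_that("F1 follows 2PR/(P+R), with the geometric variant behind a flag", {
  # traces engineered so threshold 4 gives P = 0.5, R = 1 on facial:
  # 2 true bumps (z 6), 2 false bumps (z 5 where truth is absent),
  # 2 quiet true-negatives
  mk <- function(z) toy_ztrace(z * gauss_bump(2200, 10, 4))
  traces <- tibble::tibble(
    subject_id = "S1",
    setting_id = sprintf("s%d", 1:6),
    label = "CL_nasalis", group = "facial",
    trace = list(mk(6), mk(6), mk(5), mk(5), mk(0), mk(0))
  )
  ann <- tibble::tibble(setting_id = sprintf("s%d", 1:6),
                        label = "CL_nasalis",
                        mep_present = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                        FALSE))
  sw <- f1_threshold_sweep(traces, ann, thresholds = 4)
  expect_equal(sw$sweep$precision, 0.5)
  expect_equal(sw$sweep$recall, 1)
  expect_equal(sw$sweep$f1, 2 / 3)
  swg <- f1_threshold_sweep(traces, ann, thresholds = 4,
                            f1_variant = "geometric")
  expect_equal(swg$sweep$f1, sqrt(0.5))
  # at threshold 5.5 the false bumps disappear: perfect detector, F1 = 1
  sw2 <- f1_threshold_sweep(traces, ann, thresholds = c(4, 5.5))
  expect_equal(sw2$best$threshold, 5.5)
  expect_equal(sw2$best$f1, 1)
})

test_that("the F1-optimal threshold falls in the generative margin", {
  # band-limited noise (peaks wide enough to pass the width gate, heights
  # ~<= 3.5) vs bumps of height 5: the optimum must separate them
  withr::with_seed(12, {
    bf <- signal::butter(2, 300 / (FS / 2), type = "low")
    traces <- dplyr::bind_rows(lapply(1:20, function(i) {
      truth <- i <= 10
      v <- signal::filtfilt(bf, rnorm(2200))
      v <- v / sd(v)
      if (truth) v <- v + 5 * gauss_bump(2200, 10, 4)
      tibble::tibble(subject_id = "S1", setting_id = sprintf("s%d", i),
                     label = "CL_nasalis", group = "facial",
                     trace = list(toy_ztrace(v)))
    }))
  })
  ann <- tibble::tibble(setting_id = sprintf("s%d", 1:20),
                        label = "CL_nasalis",
                        mep_present = rep(c(TRUE, FALSE), each = 10))
  sw <- f1_threshold_sweep(traces, ann, thresholds = seq(2, 8, by = 0.5))
  expect_gte(sw$best$threshold, 3)
  expect_lte(sw$best$threshold, 6)
  expect_equal(sw$best$f1, 1)
})

test_that("waveform correlation: self gives 1, negation gives -1", {
  withr::with_seed(4, v <- 6 * gauss_bump(2200, 10, 4) + rnorm(2200, 0, 0.2))
  traces <- tibble::tibble(
    subject_id = c("S1", "S1", "S2"),
    label = "CL_nasalis", group = "facial",
    trace = list(toy_ztrace(v), toy_ztrace(v), toy_ztrace(-v))
  )
  res <- waveform_correlation_analysis(traces)
  expect_equal(res$pairs$r[res$pairs$within_subject], 1)
  expect_equal(res$pairs$r[!res$pairs$within_subject], c(-1, -1))
})

test_that("within-subject waveforms correlate above across-subject ones", {
  withr::with_seed(6, {
    kernels <- lapply(1:4, function(s)
      make_mep_kernel(2200, FS, runif(1, 8, 14), 6, runif(1, 2.5, 4.5),
                      waveform_seed = 100 + s))
    traces <- dplyr::bind_rows(lapply(1:4, function(s) {
      dplyr::bind_rows(lapply(1:4, function(k) {
        tibble::tibble(subject_id = sprintf("S%d", s), label = "CL_nasalis",
                       group = "facial",
                       trace = list(toy_ztrace(kernels[[s]] +
                                                 rnorm(2200, 0, 0.5))))
      }))
    }))
  })
  res <- waveform_correlation_analysis(traces, test = TRUE)
  expect_gt(res$median_within, res$median_across)
  expect_gt(res$median_within - res$median_across, 0.3)
  expect_s3_class(res$test, "htest")
})

test_that("full-duration sweep equals plain accuracy", {
  corpus <- simulate_corpus(1, 3, seed = 14, duration_s = 2,
                            artifact_peak_range_uv = c(0, 0))
  cfg <- pipeline_config(rejection = "none")
  res <- process_corpus(corpus, cfg)
  acc <- detection_accuracy(res$detections, res$annotations)
  sw <- duration_sweep(corpus, cfg, durations_s = c(NA, 1))
  expect_equal(sw$median_accuracy[1], acc$median_accuracy)
  expect_lte(sw$accuracy[2], 1)
})

test_that("feature summary isolates the only responding muscle", {
  det <- tidyr::expand_grid(setting_id = sprintf("s%d", 1:4),
                            label = c("CL_nasalis", "CL_ECR"))
  det$status <- ifelse(det$label == "CL_nasalis", "response", "no_response")
  det$peak_z <- ifelse(det$status == "response", 6, 0)
  det$latency_ms <- ifelse(det$status == "response", 10, NA)
  s <- corpus_feature_summary(det)
  expect_equal(s$response_frequency[s$label == "CL_nasalis"], 1)
  expect_equal(s$response_frequency[s$label == "CL_ECR"], 0)
  # denominator: settings with >= 1 response counted once
  expect_equal(s$n_settings, c(4L, 4L))
})
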