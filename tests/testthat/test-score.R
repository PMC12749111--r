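# IQR normalization calibration and the aggregate mEP score.

det_row <- function(label, status, peak_z = 0, group = NULL) {
  if (is.null(group)) {
    group <- default_muscles()$group[default_muscles()$label == label]
  }
  tibble::tibble(label = label, group = group, status = status,
                 peak_z = peak_z)
}

test_that("a single-muscle corpus calibrates to scale exactly 1", {
  det <- det_row("CL_nasalis", "response", peak_z = c(5, 6, 8, 11))
  tab <- calibrate_normalization(det)
  expect_equal(tab$iqr_scale, 1)
  expect_equal(attr(tab, "pooled_iqr"), tab$muscle_iqr)
})

test_that("two-muscle calibration follows pooled IQR / muscle IQR", {
  # hand-computed oracle (type-7 quantiles, n = 5 puts q25/q75 on the 2nd
  # and 4th order statistics): A = {0,1,2,3,4} has IQR 3 - 1 = 2;
  # B = {0,2,4,6,8} has IQR 6 - 2 = 4; pooled sorted
  # {0,0,1,2,2,3,4,4,6,8} has q25 = 1 + 0.25(2-1) = 1.25 and
  # q75 = 4 + 0.75(4-4) = 4, so pooled IQR 2.75 -> scales 1.375, 0.6875
  det <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = c(0, 1, 2, 3, 4)),
    det_row("CL_ECR", "response", peak_z = c(0, 2, 4, 6, 8))
  )
  tab <- calibrate_normalization(det)
  expect_equal(attr(tab, "pooled_iqr"), 2.75)
  expect_equal(tab$iqr_scale[tab$label == "CL_nasalis"], 1.375)
  expect_equal(tab$iqr_scale[tab$label == "CL_ECR"], 0.6875)
})

test_that("after calibration every muscle's normalized IQR is the pooled IQR", {
  withr::with_seed(8, det <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 4 + rexp(40, 0.3)),
    det_row("CL_ECR", "response", peak_z = 7 + rexp(40, 0.1)),
    det_row("CL_FDI", "response", peak_z = 7 + rexp(40, 0.8))
  ))
  tab <- calibrate_normalization(det)
  pooled <- attr(tab, "pooled_iqr")
  for (lb in unique(det$label)) {
    z <- det$peak_z[det$label == lb]
    norm <- vapply(z, normalize_amplitude, numeric(1), label = lb,
                   table = tab)
    expect_lt(abs(IQR(norm) - pooled), 1e-9)
  }
})

test_that("degenerate muscles fall back to scale 1 with a warning", {
  det <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = c(5, 5, 5, 5)),  # zero IQR
    det_row("CL_ECR", "response", peak_z = c(8, 9, 11, 14))
  )
  expect_warning(tab <- calibrate_normalization(det), "zero IQR")
  expect_equal(tab$iqr_scale[tab$label == "CL_nasalis"], 1)
  det2 <- det_row("CL_FCR", "response", peak_z = c(8, 10))      # < 4 responses
  expect_warning(tab2 <- calibrate_normalization(det2), "scale set to 1")
  expect_equal(tab2$iqr_scale, 1)
})

test_that("amplitude normalization applies threshold shift, scale, add-back", {
  tab <- identity_normalization()
  expect_equal(normalize_amplitude(4, "CL_nasalis", tab), 7)   # at threshold
  tab$iqr_scale[tab$label == "CL_ECR"] <- 0.5
  expect_equal(normalize_amplitude(12, "CL_ECR", tab), (12 - 7) * 0.5 + 7)
  expect_warning(v <- normalize_amplitude(9, "CL_masseter", tab),
                 "not in normalization table")
  expect_equal(v, (9 - 7) * 1 + 7)
})

test_that("worked-example scores: silence gives 0, one minimal response 1", {
  none <- dplyr::bind_rows(lapply(default_muscles()$label[1:8], det_row,
                                  status = "no_response"))
  expect_equal(mep_score(none)$mep_score, 0)
  # facial peak_z 5 with identity scale normalizes to (5-4)+7 = 8
  one <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 5),
    lapply(default_muscles()$label[c(1:4, 6:8)], det_row,
           status = "no_response")
  )
  s <- mep_score(one)
  expect_equal(s$detections$normalized_amplitude[
    s$detections$status == "response"], 8)
  expect_equal(s$mep_score, 1)
})

test_that("mixed responses average before the log transform", {
  # normalized amplitudes {7, 9, 0, 0} -> mean 4 -> log2(5)
  det <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 4),        # -> 7
    det_row("CL_ECR", "response", peak_z = 9),            # -> 9
    det_row("CL_FCR", "no_response"),
    det_row("CL_FDI", "no_response")
  )
  expect_equal(mep_score(det)$mep_score, log2(1 + 4))
})

test_that("excluded channels leave the denominator; all-excluded is missing", {
  det <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 5),        # -> 8
    det_row("CL_ECR", "excluded"),
    det_row("CL_FCR", "no_response")
  )
  s <- mep_score(det)
  expect_equal(s$n_included, 2L)
  expect_equal(s$mep_score, log2(1 + 8 / 2))
  all_ex <- dplyr::bind_rows(
    det_row("CL_nasalis", "excluded"), det_row("CL_ECR", "excluded")
  )
  expect_true(is.na(mep_score(all_ex)$mep_score))
  expect_error(mep_score(det[0, ]), class = "mep_empty_setting")
})

test_that("the score is monotone in any responding channel's amplitude", {
  base <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 6),
    det_row("CL_ECR", "response", peak_z = 9),
    det_row("CL_FCR", "no_response")
  )
  s0 <- mep_score(base)$mep_score
  for (dz in c(0.5, 2, 10)) {
    up <- base
    up$peak_z[1] <- up$peak_z[1] + dz
    expect_gte(mep_score(up)$mep_score, s0)
  }
})

test_that("adding a channel above/below the current mean moves the score", {
  base <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 6),
    det_row("CL_ECR", "no_response")
  )
  s0 <- mep_score(base)$mep_score
  high <- dplyr::bind_rows(base, det_row("CL_FCR", "response", peak_z = 30))
  low <- dplyr::bind_rows(base, det_row("CL_FCR", "no_response"))
  expect_gt(mep_score(high)$mep_score, s0)
  expect_lt(mep_score(low)$mep_score, s0)
})

test_that("normalization tables round-trip through JSON", {
  withr::with_seed(3, det <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 4 + rexp(10)),
    det_row("CL_ECR", "response", peak_z = 7 + rexp(10))
  ))
  tab <- calibrate_normalization(det)
  path <- withr::local_tempfile(fileext = ".json")
  write_normalization(tab, path)
  back <- read_normalization(path)
  expect_equal(back$iqr_scale, tab$iqr_scale, tolerance = 1e-12)
  expect_equal(attr(back, "pooled_iqr"), attr(tab, "pooled_iqr"),
               tolerance = 1e-12)
})

test_that("tidy and glance expose the score components", {
  det <- dplyr::bind_rows(
    det_row("CL_nasalis", "response", peak_z = 5),
    det_row("CL_ECR", "no_response")
  )
  s <- mep_score(det)
  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(nrow(tidy(s)), 2L)
  g <- glance(s)
  expect_equal(g$n_responding, 1L)
  expect_equal(g$mep_score, s$mep_score)
})
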