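# Evaluation against ground-truth annotations: accuracy, F1 threshold
# sweeps, stimulation-duration sweeps, waveform-correlation analysis, and
# descriptive corpus summaries.

join_truth <- function(detections, annotations) {
  merged <- dplyr::inner_join(
    detections, annotations,
    by = intersect(c("setting_id", "label"), names(annotations))
  )
  if (nrow(merged) == 0L) {
    stop_mep("detections and annotations do not overlap", "mep_empty_overlap")
  }
  merged[merged$status != "excluded", ]
}

#' Detection accuracy per muscle
#'
#' Proportion of stimulation settings whose binary detection decision
#' matches the ground-truth annotation, per muscle; excluded channels are
#' removed from the denominator. The aggregate `median` and `min`
#' (worst-case) across muscles summarize overall performance.
#'
#' @param detections Detections tibble (`setting_id`, `label`, `status`).
#' @param annotations Annotation tibble (`setting_id`, `label`,
#'   `mep_present`).
#' @return A list: `per_muscle` tibble (`label`, `n`, `accuracy`),
#'   `median_accuracy`, `min_accuracy`.
#' @export
detection_accuracy <- function(detections, annotations) {
  m <- join_truth(detections, annotations)
  m$pred <- m$status == "response"
  per <- m |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(),
                     accuracy = mean(.data$pred == .data$mep_present),
                     .groups = "drop")
  list(per_muscle = per,
       median_accuracy = stats::median(per$accuracy),
       min_accuracy = min(per$accuracy))
}

precision_recall <- function(pred, truth) {
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  fn <- sum(!pred & truth)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  c(precision = p, recall = r)
}

#' F1 score across detection thresholds
#'
#' Re-runs peak detection on stored z-scored traces at each candidate
#' threshold and reports precision, recall and F1 per muscle group — the
#' basis for choosing group thresholds when classes are unbalanced (most
#' settings evoke no response). F1 is the harmonic mean `2PR / (P + R)`;
#' a geometric-mean variant `sqrt(PR)` is available behind
#' `f1_variant = "geometric"` for comparison studies.
#'
#' @param traces Traces tibble with z-scored traces (from
#'   [process_corpus()] with `keep_traces = TRUE`).
#' @param annotations Annotation tibble (`setting_id`, `label`,
#'   `mep_present`).
#' @param thresholds Numeric vector of candidate z thresholds.
#' @param cfg A [detection_config()] (windows and width bounds are reused;
#'   the group thresholds are overridden by each candidate).
#' @param f1_variant `"harmonic"` (default) or `"geometric"`.
#' @return A list: `sweep` tibble (`group`, `threshold`, `precision`,
#'   `recall`, `f1`) and `best` (per-group argmax row).
#' @export
f1_threshold_sweep <- function(traces, annotations, thresholds,
                               cfg = detection_config(),
                               f1_variant = c("harmonic", "geometric")) {
  f1_variant <- match.arg(f1_variant)
  stopifnot(all(thresholds > 0))
  rows <- list()
  for (thr in thresholds) {
    cfg_t <- cfg
    cfg_t$threshold_facial <- thr
    cfg_t$threshold_limb <- thr
    det <- dplyr::bind_rows(lapply(seq_len(nrow(traces)), function(i) {
      d <- detect_mep(traces$trace[[i]], cfg = cfg_t)
      d$setting_id <- traces$setting_id[i]
      d$group <- traces$group[i]
      d
    }))
    m <- join_truth(det, annotations)
    for (g in unique(m$group)) {
      mg <- m[m$group == g, ]
      pr <- unname(precision_recall(mg$status == "response", mg$mep_present))
      f1 <- if (pr[1] + pr[2] == 0) 0 else if (f1_variant == "harmonic") {
        2 * pr[1] * pr[2] / (pr[1] + pr[2])
      } else {
        sqrt(pr[1] * pr[2])
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, threshold = thr,
        precision = pr[1], recall = pr[2], f1 = f1
      )
    }
  }
  sweep <- dplyr::bind_rows(rows)
  best <- sweep |>
    dplyr::group_by(.data$group) |>
    dplyr::slice_max(.data$f1, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  list(sweep = sweep, best = best)
}

#' Waveform-correlation analysis
#'
#' Quantifies response-waveform stereotypy: pairwise Pearson correlations
#' between responding traces of the same muscle, restricted to the muscle's
#' detection window, with each pair labeled within-subject or
#' across-subject. Real evoked responses are highly correlated across
#' settings within a subject and muscle but not across subjects; the
#' medians of the two groups summarize the contrast, with an optional
#' rank-sum test.
#'
#' @param traces Traces tibble (`subject_id`, `label`, `group`, `trace`) of
#'   responding channels (z-scored or averaged).
#' @param cfg A [detection_config()] supplying per-muscle windows.
#' @param test If `TRUE`, a Wilcoxon rank-sum test compares the two groups.
#' @return A list: `pairs` tibble (`label`, `within_subject`, `r`),
#'   `median_within`, `median_across`, and `test` (htest or `NULL`).
#' @export
waveform_correlation_analysis <- function(traces, cfg = detection_config(),
                                          test = FALSE) {
  if (nrow(traces) < 2L) {
    stop_mep("need at least two responding traces", "mep_empty_overlap")
  }
  rows <- list()
  for (lb in unique(traces$label)) {
    sub <- traces[traces$label == lb, ]
    if (nrow(sub) < 2L) next
    win_ms <- muscle_window(lb, sub$group[1], cfg)
    n <- length(sub$trace[[1]]$values)
    win <- window_idx(n, sub$trace[[1]]$fs_hz, win_ms)
    M <- vapply(sub$trace, function(tr) tr$values[win], numeric(length(win)))
    for (i in seq_len(ncol(M) - 1L)) {
      for (j in (i + 1L):ncol(M)) {
        if (stats::sd(M[, i]) == 0 || stats::sd(M[, j]) == 0) next
        rows[[length(rows) + 1L]] <- tibble::tibble(
          label = lb,
          within_subject = sub$subject_id[i] == sub$subject_id[j],
          r = stats::cor(M[, i], M[, j])
        )
      }
    }
  }
  pairs <- dplyr::bind_rows(rows)
  res <- list(
    pairs = pairs,
    median_within = stats::median(pairs$r[pairs$within_subject]),
    median_across = stats::median(pairs$r[!pairs$within_subject]),
    test = NULL
  )
  if (test && nrow(pairs) > 0 && any(pairs$within_subject) &&
      any(!pairs$within_subject)) {
    res$test <- stats::wilcox.test(pairs$r[pairs$within_subject],
                                   pairs$r[!pairs$within_subject])
  }
  res
}

#' Accuracy vs stimulation duration
#'
#' Re-runs the full pipeline using only the first `d` seconds of
#' stimulation for each candidate duration and reports overall and
#' per-group accuracy — a desk-scale analogue of asking how short the
#' stimulation train can be without losing detection accuracy.
#'
#' @param corpus A [corpus_plan()] or list of simulated recordings.
#' @param config A [pipeline_config()].
#' @param durations_s Numeric vector of durations to evaluate; `NA` or the
#'   full duration means no truncation.
#' @return Tibble (`duration_s`, `n`, `accuracy`, `median_accuracy`,
#'   `min_accuracy`).
#' @export
duration_sweep <- function(corpus, config = NULL, durations_s) {
  rows <- lapply(durations_s, function(d) {
    md <- if (is.na(d)) NULL else d
    res <- process_corpus(corpus, config, max_duration_s = md)
    m <- join_truth(res$detections, res$annotations)
    acc <- detection_accuracy(res$detections, res$annotations)
    tibble::tibble(
      duration_s = d,
      n = nrow(m),
      accuracy = mean((m$status == "response") == m$mep_present),
      median_accuracy = acc$median_accuracy,
      min_accuracy = acc$min_accuracy
    )
  })
  dplyr::bind_rows(rows)
}

#' Descriptive per-muscle corpus summary
#'
#' Response frequency (share of settings in which the muscle responded,
#' out of settings where at least one muscle responded), latency
#' distribution, and amplitude distribution (raw z and, when a
#' normalization table is given, normalized) per muscle. Purely
#' descriptive; no inferential statistics.
#'
#' @param detections Detections tibble from [process_corpus()].
#' @param table Optional `normalization_table`.
#' @return Tibble, one row per muscle, with response counts/frequency and
#'   latency/amplitude quartiles.
#' @export
corpus_feature_summary <- function(detections, table = NULL) {
  active <- detections |>
    dplyr::group_by(.data$setting_id) |>
    dplyr::summarise(any_resp = any(.data$status == "response"),
                     .groups = "drop")
  denom_ids <- active$setting_id[active$any_resp]
  if (length(denom_ids) == 0L) {
    stop_mep("no setting with a detected response", "mep_empty_overlap")
  }
  d <- detections[detections$setting_id %in% denom_ids, ]
  if (!is.null(table)) {
    d$normalized_amplitude <- vapply(seq_len(nrow(d)), function(i) {
      if (d$status[i] == "response") {
        normalize_amplitude(d$peak_z[i], d$label[i], table)
      } else NA_real_
    }, numeric(1))
  }
  q <- function(x, p) if (length(x) == 0) NA_real_ else
    unname(stats::quantile(x, p))
  d |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(
      n_settings = dplyr::n(),
      n_responses = sum(.data$status == "response"),
      response_frequency = .data$n_responses / length(denom_ids),
      pct_excluded = mean(.data$status == "excluded"),
      latency_q25 = q(.data$latency_ms[.data$status == "response"], 0.25),
      latency_median = q(.data$latency_ms[.data$status == "response"], 0.5),
      latency_q75 = q(.data$latency_ms[.data$status == "response"], 0.75),
      amp_z_q25 = q(.data$peak_z[.data$status == "response"], 0.25),
      amp_z_median = q(.data$peak_z[.data$status == "response"], 0.5),
      amp_z_q75 = q(.data$peak_z[.data$status == "response"], 0.75),
      amp_norm_median = if (!is.null(table))
        q(.data$normalized_amplitude[.data$status == "response"], 0.5)
        else NA_real_,
      .groups = "drop"
    )
}
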