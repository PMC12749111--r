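# End-to-end processing: averaging -> exclusion -> group-specific cleaning
# -> z-scoring -> detection -> scoring.

#' Pipeline configuration
#'
#' Wires the group-specific cleaning choices to the detection and scoring
#' stages. Defaults follow the best-performing combination: template-based
#' artifact rejection on facial channels (whose short response latencies
#' overlap the stimulation artifact), the subtractive 60 Hz notch on limb
#' channels (where line noise dominates; it does not help facial
#' detection and is off there), and no Butterworth band filtering (the
#' band edges are available but disabled by default).
#'
#' @param rejection Facial artifact rejection method: `"template"`
#'   (default), `"pca"`, `"template_pca"`, or `"none"`.
#' @param pca_subset,pca_scaling Options for the PCA-based methods (see
#'   [pca_reject()]).
#' @param notch_limb,notch_facial Apply [subtractive_notch()] per group.
#' @param butter_facial,butter_limb Optional length-2 `c(low_hz, high_hz)`
#'   band (either element may be `NA` for one-sided filtering); `NULL`
#'   disables.
#' @param detection A [detection_config()].
#' @param var_threshold,abs_threshold Exclusion thresholds (see
#'   [apply_exclusion()]).
#' @param template_library A `template_library`, required when `rejection`
#'   is `"template"` or `"template_pca"`.
#' @param normalization A `normalization_table` or `NULL` (identity).
#' @return A list with class `"pipeline_config"`.
#' @export
pipeline_config <- function(rejection = c("template", "pca", "template_pca",
                                          "none"),
                            pca_subset = "facial_only",
                            pca_scaling = "median_scaling",
                            notch_limb = TRUE,
                            notch_facial = FALSE,
                            butter_facial = NULL,
                            butter_limb = NULL,
                            detection = detection_config(),
                            var_threshold = 150,
                            abs_threshold = 25,
                            template_library = NULL,
                            normalization = NULL) {
  rejection <- match.arg(rejection)
  if (rejection %in% c("template", "template_pca") &&
      is.null(template_library)) {
    stop_mep(sprintf("rejection method '%s' requires a template_library",
                     rejection), "mep_missing_library")
  }
  structure(
    list(rejection = rejection, pca_subset = pca_subset,
         pca_scaling = pca_scaling, notch_limb = isTRUE(notch_limb),
         notch_facial = isTRUE(notch_facial),
         butter_facial = butter_facial, butter_limb = butter_limb,
         detection = detection, var_threshold = var_threshold,
         abs_threshold = abs_threshold,
         template_library = template_library,
         normalization = normalization),
    class = "pipeline_config"
  )
}

apply_band <- function(trace, band) {
  lo <- if (is.na(band[1])) NULL else band[1]
  hi <- if (length(band) < 2 || is.na(band[2])) NULL else band[2]
  butter_zero_phase(trace, low_hz = lo, high_hz = hi)
}

#' Run the full detection and scoring pipeline on one recording
#'
#' For a single stimulation setting: pulse-triggered averaging; per-channel
#' exclusion of noisy traces; artifact rejection on the non-excluded facial
#' channels (operating on the microvolt-scale averaged traces, before
#' z-scoring); subtractive notch per group; baseline z-scoring (channels
#' with a degenerate flat baseline are auto-excluded); latency-windowed
#' peak detection; and aggregation into the setting's mEP score. The whole
#' chain is deterministic given its inputs.
#'
#' @param rec A [raw_recording()].
#' @param config A [pipeline_config()].
#' @param max_duration_s Optional cap on the stimulation time used (see
#'   [epoch_average()]).
#' @param keep_traces If `TRUE`, the cleaned z-scored traces are attached
#'   to the result (`$traces`), for evaluation analyses.
#' @return A `setting_score` whose `detections` tibble carries one row per
#'   channel (`label`, `group`, `status`, `peak_z`, `peak_uv`,
#'   `latency_ms`, `width_ms`, `threshold_used`, `normalized_amplitude`)
#'   plus `subject_id` / `setting_id`.
#' @export
run_pipeline <- function(rec, config = NULL, max_duration_s = NULL,
                         keep_traces = FALSE) {
  if (is.null(config)) {
    config <- pipeline_config(rejection = "none")
  }
  traces <- epoch_average(rec, max_duration_s = max_duration_s)
  excluded <- vapply(traces$trace, apply_exclusion, logical(1),
                     var_threshold = config$var_threshold,
                     abs_threshold = config$abs_threshold)

  # artifact rejection on non-excluded facial channels (microvolt scale)
  usable <- traces[!excluded, ]
  if (nrow(usable) > 0 && any(usable$group == "facial") &&
      config$rejection != "none") {
    cleaned <- switch(config$rejection,
      template = {
        for (i in which(usable$group == "facial")) {
          usable$trace[[i]] <- template_reject(usable$trace[[i]],
                                               config$template_library)
        }
        usable
      },
      pca = pca_reject(usable, channel_subset = config$pca_subset,
                       scaling = config$pca_scaling),
      template_pca = template_pca_reject(usable, config$template_library,
                                         scaling = config$pca_scaling)
    )
    usable <- cleaned
  }

  detections <- vector("list", nrow(traces))
  ztraces <- vector("list", nrow(traces))
  ui <- cumsum(!excluded)            # row in `usable` for each trace row
  for (i in seq_len(nrow(traces))) {
    mu_label <- traces$label[i]
    thr <- group_threshold(traces$group[i], config$detection)
    if (excluded[i]) {
      detections[[i]] <- empty_detection("excluded", thr, mu_label)
      next
    }
    tr <- usable$trace[[ui[i]]]
    notch_on <- if (traces$group[i] == "facial") config$notch_facial
                else config$notch_limb
    if (notch_on) tr <- subtractive_notch(tr)
    band <- if (traces$group[i] == "facial") config$butter_facial
            else config$butter_limb
    if (!is.null(band)) tr <- apply_band(tr, band)
    zt <- tryCatch(baseline_zscore(tr), mep_degenerate_baseline = function(e) NULL)
    if (is.null(zt)) {
      detections[[i]] <- empty_detection("excluded", thr, mu_label)
      next
    }
    ztraces[[i]] <- zt
    detections[[i]] <- detect_mep(zt, cfg = config$detection)
  }
  det <- dplyr::bind_rows(detections)
  det <- tibble::add_column(det,
                            subject_id = rec$subject_id,
                            setting_id = rec$setting$setting_id,
                            group = traces$group,
                            .before = 1)
  out <- mep_score(det, table = config$normalization)
  if (keep_traces) {
    keep <- !vapply(ztraces, is.null, logical(1))
    out$traces <- tibble::tibble(
      subject_id = rec$subject_id,
      setting_id = rec$setting$setting_id,
      label = traces$label[keep],
      group = traces$group[keep],
      trace = ztraces[keep]
    )
  }
  out
}

#' Process a corpus of recordings
#'
#' Runs [run_pipeline()] over a list of simulated recordings or,
#' memory-efficiently, over a [corpus_plan()] realized one row at a time.
#'
#' @param corpus A [corpus_plan()] tibble, or a list of
#'   `list(recording, annotations)` as produced by [simulate_corpus()].
#' @param config A [pipeline_config()].
#' @param max_duration_s Optional stimulation-duration cap.
#' @param keep_traces If `TRUE`, cleaned z-scored traces of non-excluded
#'   channels are collected (memory permitting).
#' @return A list with `detections` (tibble, one row per setting x
#'   channel), `scores` (tibble, one row per setting), `annotations`
#'   (ground truth, when available), and `traces` (when requested).
#' @export
process_corpus <- function(corpus, config = NULL, max_duration_s = NULL,
                           keep_traces = FALSE) {
  is_plan <- tibble::is_tibble(corpus)
  n <- if (is_plan) nrow(corpus) else length(corpus)
  dets <- vector("list", n)
  scores <- vector("list", n)
  anns <- vector("list", n)
  trs <- vector("list", n)
  for (i in seq_len(n)) {
    item <- if (is_plan) realize_recording(corpus, i) else corpus[[i]]
    res <- run_pipeline(item$recording, config,
                        max_duration_s = max_duration_s,
                        keep_traces = keep_traces)
    dets[[i]] <- res$detections
    scores[[i]] <- tibble::tibble(
      subject_id = item$recording$subject_id,
      setting_id = item$recording$setting$setting_id,
      amplitude_ma = item$recording$setting$amplitude_ma,
      contact_config = item$recording$setting$contact_config,
      mep_score = res$mep_score,
      n_included = res$n_included,
      n_responding = res$n_responding
    )
    anns[[i]] <- item$annotations
    if (keep_traces) trs[[i]] <- res$traces
  }
  out <- list(
    detections = dplyr::bind_rows(dets),
    scores = dplyr::bind_rows(scores),
    annotations = dplyr::bind_rows(anns)
  )
  if (keep_traces) out$traces <- dplyr::bind_rows(trs)
  out
}
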