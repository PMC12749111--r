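# Reading and writing recordings (CSV matrix + JSON metadata, or EDF) and
# result files. On disk, pulse onsets are 0-based sample indices; in memory
# they are 1-based (converted here, at the boundary).

channels_from_meta <- function(meta_channels) {
  dplyr::bind_rows(lapply(meta_channels, function(ch) {
    if (is.character(ch)) return(muscle_channel(ch))
    muscle_channel(
      ch$label,
      group = ch$group %||% NULL,
      laterality = ch$laterality %||% NULL,
      detection_window_ms = if (!is.null(ch$detection_window_ms)) {
        as.numeric(ch$detection_window_ms)
      } else NULL
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording from disk
#'
#' Accepts either an EDF/EDF+ file or a CSV signal matrix (samples in rows,
#' one column per channel, header row of labels). The JSON metadata file
#' supplies the channel descriptions, the stimulation setting, and the
#' pulse onsets — either explicitly (`pulse_onsets`, 0-based sample
#' indices) or as the name of a stimulus-sync channel (`sync_channel`) from
#' which onsets are detected by threshold crossing. Signal units are
#' microvolts (EDF channels declaring mV are converted).
#'
#' @param path Signal file (`.edf` or `.csv`).
#' @param metadata_path JSON metadata; defaults to `<path>.json`.
#' @return A [raw_recording()].
#' @export
read_recording <- function(path, metadata_path = NULL) {
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".json")
  if (!file.exists(metadata_path)) {
    stop_mep(sprintf("metadata file not found: %s", metadata_path),
             "mep_unparseable")
  }
  meta <- jsonlite::read_json(metadata_path, simplifyVector = FALSE)
  is_edf <- grepl("\\.edf$", path, ignore.case = TRUE)
  if (is_edf) {
    edf <- read_edf(path)
    sig <- edf$signal
    labels <- edf$labels
    fs <- meta$fs_hz %||% edf$fs_hz
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    sig <- t(as.matrix(df))
    labels <- colnames(df)
    fs <- meta$fs_hz
    if (is.null(fs)) stop_mep("metadata must supply fs_hz", "mep_unparseable")
  }
  meta_ch <- channels_from_meta(meta$channels)
  sync_name <- meta$sync_channel %||% NULL
  keep <- setdiff(labels, sync_name)
  if (!setequal(keep, meta_ch$label) || length(keep) != nrow(meta_ch)) {
    stop_mep(sprintf("metadata lists %d channels (%s) but file has %d (%s)",
                     nrow(meta_ch), paste(meta_ch$label, collapse = ","),
                     length(keep), paste(keep, collapse = ",")),
             "mep_channel_mismatch")
  }
  setting <- stim_setting(
    amplitude_ma = meta$setting$amplitude_ma,
    pulse_width_us = meta$setting$pulse_width_us %||% 60,
    frequency_hz = meta$setting$frequency_hz %||% 10,
    duration_s = meta$setting$duration_s %||% 12,
    contact_config = meta$setting$contact_config %||% "2",
    setting_id = meta$setting$setting_id %||% NULL
  )
  if (!is.null(meta$pulse_onsets)) {
    onsets <- unlist(meta$pulse_onsets) + 1L      # 0-based on disk
  } else if (!is.null(sync_name)) {
    onsets <- detect_pulse_onsets(sig[match(sync_name, labels), ], fs,
                                  frequency_hz = setting$frequency_hz)
  } else {
    stop_mep("metadata must supply pulse_onsets or sync_channel",
             "mep_invalid_onsets")
  }
  raw_recording(
    sig[match(meta_ch$label, labels), , drop = FALSE],
    fs_hz = fs, pulse_onsets = onsets, channels = meta_ch,
    setting = setting,
    subject_id = meta$subject_id %||% "S1",
    lead_id = meta$lead_id %||% "L1"
  )
}

#' Write a recording to disk
#'
#' CSV signal matrix (samples in rows, header row of channel labels,
#' microvolts) plus JSON metadata readable by [read_recording()]. Pulse
#' onsets are written 0-based.
#'
#' @param rec A [raw_recording()].
#' @param path CSV path (or `.edf` to write EDF).
#' @param metadata_path JSON path; defaults to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, metadata_path = NULL) {
  if (is.null(metadata_path)) metadata_path <- paste0(path, ".json")
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    write_edf(rec, path)
  } else {
    df <- as.data.frame(t(rec$signal))
    colnames(df) <- rec$channels$label
    utils::write.csv(df, path, row.names = FALSE)
  }
  meta <- list(
    fs_hz = rec$fs_hz,
    pulse_onsets = rec$pulse_onsets - 1L,
    channels = lapply(seq_len(nrow(rec$channels)), function(i) {
      ch <- rec$channels[i, ]
      list(label = ch$label, group = ch$group, laterality = ch$laterality,
           detection_window_ms = c(ch$window_low_ms, ch$window_high_ms))
    }),
    setting = rec$setting[c("amplitude_ma", "pulse_width_us", "frequency_hz",
                            "duration_s", "contact_config", "setting_id")],
    subject_id = rec$subject_id,
    lead_id = rec$lead_id
  )
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-setting results
#'
#' One CSV row per setting x channel (status, peak height in z and
#' microvolts, latency, width, normalized amplitude) plus a JSON summary
#' with one mEP score per setting. Column order is fixed.
#'
#' @param results A `setting_score` or non-empty list of them.
#' @param path CSV path; the JSON summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "setting_score")) results <- list(results)
  if (length(results) == 0L) {
    stop_mep("results must be non-empty", "mep_empty_results")
  }
  cols <- c("setting_id", "label", "status", "peak_z", "peak_uv",
            "latency_ms", "width_ms", "threshold_used",
            "normalized_amplitude")
  rows <- dplyr::bind_rows(lapply(results, function(r) r$detections))
  if (!"setting_id" %in% names(rows)) rows$setting_id <- NA_character_
  utils::write.csv(as.data.frame(rows[, cols]), path, row.names = FALSE)
  summary <- lapply(results, function(r) {
    list(
      setting_id = r$detections$setting_id[1] %||% NA,
      mep_score = r$mep_score,
      n_included = r$n_included,
      n_responding = r$n_responding
    )
  })
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read results written by [write_results()]
#'
#' @param path CSV path (as passed to the writer).
#' @return A list: `channels` (tibble of per-channel rows) and `summary`
#'   (tibble of per-setting scores).
#' @export
read_results <- function(path) {
  channels <- tibble::as_tibble(utils::read.csv(path))
  summary <- tibble::as_tibble(
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  )
  list(channels = channels, summary = summary)
}
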