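# Cross-muscle amplitude normalization and the aggregate mEP score.

#' Calibrate per-muscle IQR normalization
#'
#' Different muscles have very differently scaled (and heavily skewed)
#' response-amplitude distributions. To make amplitudes comparable, each
#' muscle's detected peak amplitudes (in baseline z units) are rescaled so
#' that its interquartile range matches the pooled all-muscle IQR: the
#' scaling factor is `pooled IQR / muscle IQR`.
#'
#' @param detections A detections tibble with columns `label`, `status`,
#'   `peak_z` (and ideally `group`), pooled across settings.
#' @param cfg A [detection_config()] supplying the group thresholds stored
#'   alongside the scales.
#' @param min_responses Muscles with fewer detected responses than this
#'   keep scale 1 (with a warning); the default 4 is the minimum for a
#'   meaningful IQR.
#' @return A `normalization_table`: tibble (`label`, `group`, `n_responses`,
#'   `muscle_iqr`, `iqr_scale`) with attributes `pooled_iqr` and
#'   `add_back` (= 7, the limb threshold re-added after scaling).
#' @export
calibrate_normalization <- function(detections, cfg = detection_config(),
                                    min_responses = 4) {
  resp <- detections[detections$status == "response", ]
  if (nrow(resp) == 0L) {
    stop_mep("no detected responses to calibrate on", "mep_empty_calibration")
  }
  pooled <- stats::IQR(resp$peak_z)
  labels <- unique(detections$label)
  grp <- if ("group" %in% names(detections)) {
    stats::setNames(detections$group, detections$label)
  } else {
    stats::setNames(default_muscles()$group, default_muscles()$label)
  }
  tab <- dplyr::bind_rows(lapply(labels, function(lb) {
    z <- resp$peak_z[resp$label == lb]
    iqr <- if (length(z) >= 2) stats::IQR(z) else 0
    scale <- if (length(z) < min_responses) {
      warning(sprintf("muscle %s: %d responses (< %d); scale set to 1",
                      lb, length(z), min_responses))
      1
    } else if (iqr == 0) {
      warning(sprintf("muscle %s: zero IQR; scale set to 1", lb))
      1
    } else {
      pooled / iqr
    }
    tibble::tibble(label = lb, group = unname(grp[lb]),
                   n_responses = length(z), muscle_iqr = iqr,
                   iqr_scale = scale)
  }))
  structure(tab, class = c("normalization_table", class(tab)),
            pooled_iqr = pooled, add_back = 7,
            threshold_facial = cfg$threshold_facial,
            threshold_limb = cfg$threshold_limb)
}

#' Identity normalization table
#'
#' All scales 1 — the shipped default until a corpus has been calibrated.
#'
#' @param labels Muscle labels to cover (default: the canonical set).
#' @param cfg A [detection_config()].
#' @return A `normalization_table`.
#' @export
identity_normalization <- function(labels = default_muscles()$label,
                                   cfg = detection_config()) {
  grp <- stats::setNames(default_muscles()$group, default_muscles()$label)
  tab <- tibble::tibble(label = labels,
                        group = unname(grp[labels]),
                        n_responses = 0L, muscle_iqr = NA_real_,
                        iqr_scale = 1)
  structure(tab, class = c("normalization_table", class(tab)),
            pooled_iqr = NA_real_, add_back = 7,
            threshold_facial = cfg$threshold_facial,
            threshold_limb = cfg$threshold_limb)
}

#' Normalize a detected response amplitude
#'
#' Maps a detected peak (z units) onto the common cross-muscle scale:
#' subtract the muscle group's detection threshold, multiply by the
#' muscle's IQR scaling factor, then add back the limb detection threshold
#' (7) so all muscles share one origin. Negative results are floored at 0
#' (they cannot occur for responses detected at or above threshold, but the
#' guard keeps custom thresholds safe). Unknown muscles get scale 1 with a
#' warning.
#'
#' @param peak_z Detected rectified peak height, z units.
#' @param label Muscle label.
#' @param table A `normalization_table`.
#' @return Normalized amplitude (>= 0).
#' @export
normalize_amplitude <- function(peak_z, label, table) {
  row <- table[table$label == label, ]
  if (nrow(row) != 1L) {
    warning(sprintf("muscle %s not in normalization table; scale 1", label))
    grp <- if (label %in% default_muscles()$label) {
      default_muscles()$group[default_muscles()$label == label]
    } else "limb"
    row <- tibble::tibble(label = label, group = grp, iqr_scale = 1)
  }
  thr <- if (row$group == "facial") attr(table, "threshold_facial")
         else attr(table, "threshold_limb")
  max(0, (peak_z - thr) * row$iqr_scale + attr(table, "add_back"))
}

#' Aggregate mEP score for one stimulation setting
#'
#' Combines the per-muscle detection outcomes into one number quantifying
#' capsular activation: excluded channels are dropped from the denominator,
#' responding channels contribute their normalized amplitude
#' ([normalize_amplitude()]), non-responding channels contribute 0; the
#' contributions are averaged and log-compressed,
#' `score = log2(1 + mean)` (0 when no muscle responded). The scale is
#' designed to be readable: 0 = no response anywhere, about 1 = a single
#' minimal response, about 6 = strong activation of every muscle. The
#' computation uses no knowledge of the stimulation parameters.
#'
#' @param detections A detections tibble (one row per channel: `label`,
#'   `status`, `peak_z`; `status` one of `"excluded"`, `"no_response"`,
#'   `"response"`).
#' @param table A `normalization_table`; identity scales when `NULL`.
#' @return A `setting_score`: list with `mep_score` (NA when every channel
#'   was excluded), `n_included`, `n_responding`, the per-channel
#'   `detections` tibble augmented with a `normalized_amplitude` column,
#'   and the normalization table used.
#' @export
mep_score <- function(detections, table = NULL) {
  if (nrow(detections) < 1L) {
    stop_mep("at least one channel detection is required", "mep_empty_setting")
  }
  if (is.null(table)) {
    table <- identity_normalization(unique(detections$label))
  }
  detections$normalized_amplitude <- vapply(seq_len(nrow(detections)),
    function(i) {
      d <- detections[i, ]
      if (d$status == "response") {
        normalize_amplitude(d$peak_z, d$label, table)
      } else if (d$status == "no_response") 0 else NA_real_
    }, numeric(1))
  included <- detections$status != "excluded"
  n_inc <- sum(included)
  n_resp <- sum(detections$status == "response")
  score <- if (n_inc == 0L) {
    NA_real_                      # flagged missing, distinct from 0
  } else {
    m <- mean(detections$normalized_amplitude[included])
    if (m == 0) 0 else log2(1 + m)
  }
  structure(
    list(mep_score = score, n_included = n_inc, n_responding = n_resp,
         detections = detections, normalization = table),
    class = "setting_score"
  )
}

#' @export
print.setting_score <- function(x, ...) {
  cat(sprintf("<setting_score> mEP score %.3f (%d/%d channels responding, %d included)\n",
              x$mep_score, x$n_responding, nrow(x$detections), x$n_included))
  invisible(x)
}

#' Persist / load a normalization table
#'
#' @param table A `normalization_table`.
#' @param path JSON path.
#' @return `read_normalization()` returns the table; the writer returns
#'   `path` invisibly.
#' @export
write_normalization <- function(table, path) {
  jsonlite::write_json(
    list(
      pooled_iqr = attr(table, "pooled_iqr"),
      add_back = attr(table, "add_back"),
      threshold_facial = attr(table, "threshold_facial"),
      threshold_limb = attr(table, "threshold_limb"),
      muscles = as.data.frame(table)
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tab <- tibble::as_tibble(obj$muscles)
  structure(tab, class = c("normalization_table", class(tab)),
            pooled_iqr = obj$pooled_iqr, add_back = obj$add_back,
            threshold_facial = obj$threshold_facial,
            threshold_limb = obj$threshold_limb)
}
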