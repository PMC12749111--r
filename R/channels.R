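#' Canonical muscle channel table
#'
#' The muscles commonly instrumented during subthalamic DBS surgery, with
#' their group (facial vs limb), laterality relative to the stimulated
#' hemisphere (CL = contralateral, IL = ipsilateral), and the default
#' peak-detection latency window in milliseconds after the stimulation pulse.
#' Facial muscles respond at short latency (about 5-18 ms, overlapping the
#' stimulation artifact), limb muscles at longer latency (about 11-31 ms)
#' consistent with corticospinal path length.
#'
#' @return A tibble with columns `label`, `group`, `laterality`,
#'   `window_low_ms`, `window_high_ms`.
#' @export
#' @examples
#' default_muscles()
default_muscles <- function() {
  tibble::tribble(
    ~label,             ~group,   ~laterality, ~window_low_ms, ~window_high_ms,
    "CL_ECR",           "limb",   "CL",        16.5,           30.5,
    "CL_FCR",           "limb",   "CL",        14.5,           29.5,
    "CL_FDI",           "limb",   "CL",        21.0,           30.0,
    "CL_bicep",         "limb",   "CL",        11.0,           29.0,
    "CL_genioglossus",  "facial", "CL",        5.0,            18.0,
    "CL_nasalis",       "facial", "CL",        5.0,            18.0,
    "CL_orb_oris",      "facial", "CL",        5.0,            18.5,
    "IL_genioglossus",  "facial", "IL",        5.0,            18.0,
    "IL_nasalis",       "facial", "IL",        5.0,            18.0,
    "IL_orb_oris",      "facial", "IL",        5.0,            18.5
  )
}

#' Describe an EMG muscle channel
#'
#' Builds a one-row channel descriptor. For the canonical muscles (see
#' [default_muscles()]) the group, laterality and detection window are filled
#' in automatically from the label; non-canonical labels must supply them.
#'
#' @param label Channel label, e.g. `"CL_ECR"`.
#' @param group `"facial"` or `"limb"`. The group determines the default
#'   detection threshold (facial Z = 4, limb Z = 7).
#' @param laterality `"CL"` (contralateral) or `"IL"` (ipsilateral).
#' @param detection_window_ms Length-2 numeric, the peak latency window in ms.
#' @return A one-row tibble with the same columns as [default_muscles()].
#' @export
#' @examples
#' muscle_channel("CL_nasalis")
#' muscle_channel("CL_masseter", group = "facial", laterality = "CL",
#'                detection_window_ms = c(5, 18))
muscle_channel <- function(label, group = NULL, laterality = NULL,
                           detection_window_ms = NULL) {
  stopifnot(is.character(label), length(label) == 1L)
  canon <- default_muscles()
  hit <- canon[canon$label == label, ]
  if (nrow(hit) == 1L) {
    if (is.null(group)) group <- hit$group
    if (is.null(laterality)) laterality <- hit$laterality
    if (is.null(detection_window_ms)) {
      detection_window_ms <- c(hit$window_low_ms, hit$window_high_ms)
    }
  }
  if (is.null(group) || is.null(laterality) || is.null(detection_window_ms)) {
    stop_mep(
      sprintf("channel '%s' is not canonical; supply group, laterality and detection_window_ms", label),
      "mep_unknown_channel"
    )
  }
  group <- match.arg(group, c("facial", "limb"))
  laterality <- match.arg(laterality, c("CL", "IL"))
  if (length(detection_window_ms) != 2L ||
      !(0 < detection_window_ms[1]) ||
      !(detection_window_ms[1] < detection_window_ms[2])) {
    stop_mep("detection_window_ms must satisfy 0 < low < high",
             "mep_invalid_window")
  }
  tibble::tibble(
    label = label, group = group, laterality = laterality,
    window_low_ms = detection_window_ms[1],
    window_high_ms = detection_window_ms[2]
  )
}

#' Detection configuration
#'
#' Collects every tunable of the peak-detection stage: the per-group
#' z-thresholds, the per-muscle latency windows, the admissible peak width
#' range, and the wide exploratory windows used before muscle-specific
#' windows have been derived from data.
#'
#' @param threshold_facial,threshold_limb Detection thresholds in baseline
#'   z units (defaults 4 and 7).
#' @param windows Tibble of per-muscle windows (`label`, `window_low_ms`,
#'   `window_high_ms`); defaults to the canonical table.
#' @param width_bounds_ms Admissible peak width at half maximum, ms.
#' @param wide_facial_ms,wide_limb_ms Wide exploratory windows per group.
#' @param use_wide_windows If `TRUE`, detection ignores the per-muscle
#'   windows and uses the wide group windows (used when deriving windows
#'   from a new corpus).
#' @return A list with class `"detection_config"`.
#' @export
detection_config <- function(threshold_facial = 4,
                             threshold_limb = 7,
                             windows = default_muscles(),
                             width_bounds_ms = c(1, 15),
                             wide_facial_ms = c(4, 25),
                             wide_limb_ms = c(10, 40),
                             use_wide_windows = FALSE) {
  check_scalar(threshold_facial, "threshold_facial", positive = TRUE)
  check_scalar(threshold_limb, "threshold_limb", positive = TRUE)
  stopifnot(width_bounds_ms[1] < width_bounds_ms[2],
            wide_facial_ms[1] < wide_facial_ms[2],
            wide_limb_ms[1] < wide_limb_ms[2])
  structure(
    list(
      threshold_facial = threshold_facial,
      threshold_limb = threshold_limb,
      windows = windows,
      width_bounds_ms = width_bounds_ms,
      wide_facial_ms = wide_facial_ms,
      wide_limb_ms = wide_limb_ms,
      use_wide_windows = isTRUE(use_wide_windows)
    ),
    class = "detection_config"
  )
}

group_threshold <- function(group, cfg) {
  ifelse(group == "facial", cfg$threshold_facial, cfg$threshold_limb)
}

wide_window <- function(group, cfg) {
  if (group == "facial") cfg$wide_facial_ms else cfg$wide_limb_ms
}

# Latency window for one muscle under a config: muscle-specific if known
# (and not overridden), else the wide group window.
muscle_window <- function(label, group, cfg) {
  if (!cfg$use_wide_windows) {
    hit <- cfg$windows[cfg$windows$label == label, ]
    if (nrow(hit) == 1L) {
      return(c(hit$window_low_ms, hit$window_high_ms))
    }
  }
  wide_window(group, cfg)
}
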