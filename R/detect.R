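# Latency-windowed peak detection on the rectified z-scored trace.

# Local maxima with plateau handling: runs of equal values flanked by lower
# values count as one peak at the plateau center.
find_local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i > 1L && r$values[i - 1L] < r$values[i]
    right_ok <- i < k && r$values[i + 1L] < r$values[i]
    if (left_ok && right_ok) {
      out <- c(out, floor((starts[i] + ends[i]) / 2))
    }
  }
  out
}

# Width at half of the peak's height on the rectified trace, by linear
# interpolation at the half-height crossings nearest the peak. NA when a
# crossing is never reached before the epoch edge.
half_height_width_ms <- function(x, peak_idx, fs_hz) {
  h <- x[peak_idx] / 2
  n <- length(x)
  left <- NA_real_
  i <- peak_idx
  while (i > 1L) {
    i <- i - 1L
    if (x[i] < h) {
      left <- i + (h - x[i]) / (x[i + 1L] - x[i])
      break
    }
  }
  right <- NA_real_
  i <- peak_idx
  while (i < n) {
    i <- i + 1L
    if (x[i] < h) {
      right <- i - (h - x[i]) / (x[i - 1L] - x[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) return(NA_real_)
  (right - left) / fs_hz * 1000
}

empty_detection <- function(status, threshold, label = NA_character_) {
  tibble::tibble(
    label = label, status = status,
    peak_z = 0, peak_uv = 0, latency_ms = NA_real_, width_ms = NA_real_,
    threshold_used = threshold
  )
}

#' Detect an evoked response on one channel
#'
#' Rectifies the baseline z-scored trace and searches its local maxima for a
#' qualifying response peak: height at least the group threshold (facial
#' Z = 4, limb Z = 7 by default), peak latency inside the muscle's window,
#' and width at half of the peak height between 1 and 15 ms — the
#' characteristic width range of surface-recorded evoked responses, which
#' rejects both single-sample noise spikes and broad slow fluctuations.
#' Among qualifying peaks the greatest height wins (earliest latency on
#' ties).
#'
#' @param ztrace A `zscored_trace` from [baseline_zscore()].
#' @param muscle One-row channel tibble; defaults to the trace's own channel.
#' @param cfg A [detection_config()].
#' @return A one-row tibble (`label`, `status`, `peak_z`, `peak_uv`,
#'   `latency_ms`, `width_ms`, `threshold_used`); `status` is `"response"`
#'   or `"no_response"`, `peak_uv` is the rectified height rescaled to
#'   microvolts via the baseline sd.
#' @export
detect_mep <- function(ztrace, muscle = NULL, cfg = detection_config()) {
  stopifnot(inherits(ztrace, "zscored_trace"))
  if (is.null(muscle)) muscle <- ztrace$channel
  thr <- group_threshold(muscle$group, cfg)
  win_ms <- muscle_window(muscle$label, muscle$group, cfg)
  n <- length(ztrace$values)
  epoch_ms <- n / ztrace$fs_hz * 1000
  if (win_ms[2] >= epoch_ms) {
    stop_mep("detection window extends beyond the epoch", "mep_invalid_window")
  }
  r <- abs(ztrace$values)
  peaks <- find_local_maxima(r)
  t_ms <- epoch_time_ms(n, ztrace$fs_hz)
  peaks <- peaks[t_ms[peaks] >= win_ms[1] & t_ms[peaks] <= win_ms[2] &
                   r[peaks] >= thr]
  if (length(peaks) > 0L) {
    widths <- vapply(peaks, function(p) half_height_width_ms(r, p, ztrace$fs_hz),
                     numeric(1))
    ok <- !is.na(widths) & widths >= cfg$width_bounds_ms[1] &
      widths <= cfg$width_bounds_ms[2]
    peaks <- peaks[ok]
    widths <- widths[ok]
  }
  if (length(peaks) == 0L) {
    return(empty_detection("no_response", thr, muscle$label))
  }
  best <- order(-r[peaks], t_ms[peaks])[1]   # greatest height, earliest tie
  p <- peaks[best]
  tibble::tibble(
    label = muscle$label,
    status = "response",
    peak_z = r[p],
    peak_uv = r[p] * ztrace$baseline_sd_uv,
    latency_ms = t_ms[p],
    width_ms = widths[best],
    threshold_used = thr
  )
}

#' Derive muscle-specific latency windows from a corpus
#'
#' After running detection with the wide exploratory group windows (facial
#' 4-25 ms, limb 10-40 ms) over a corpus, the distribution of detected peak
#' latencies yields tighter prospective windows per muscle: the 1st to 99th
#' percentile span padded by 0.5 ms, clipped to the wide window and rounded
#' to 0.5 ms. Muscles with fewer than `min_responses` detections keep the
#' wide window (with a warning).
#'
#' @param detections A detections tibble (rows with `status`, `label`,
#'   `latency_ms`; typically from [process_corpus()] run with
#'   `use_wide_windows = TRUE`).
#' @param cfg A [detection_config()] supplying the wide windows.
#' @param groups Optional named lookup label -> group; defaults to the
#'   canonical table plus any groups present in `detections`.
#' @param min_responses Minimum detections per muscle (default 20).
#' @return A windows tibble (`label`, `window_low_ms`, `window_high_ms`,
#'   `n_responses`, `derived`).
#' @export
derive_latency_windows <- function(detections, cfg = detection_config(),
                                   groups = NULL, min_responses = 20) {
  resp <- detections[detections$status == "response", ]
  if (is.null(groups)) {
    groups <- stats::setNames(default_muscles()$group, default_muscles()$label)
    if ("group" %in% names(detections)) {
      extra <- unique(detections[, c("label", "group")])
      groups[extra$label] <- extra$group
    }
  }
  labels <- unique(detections$label)
  out <- lapply(labels, function(lb) {
    lat <- resp$latency_ms[resp$label == lb]
    wide <- wide_window(groups[[lb]], cfg)
    if (length(lat) < min_responses) {
      warning(sprintf("muscle %s: only %d responses; keeping wide window",
                      lb, length(lat)))
      return(tibble::tibble(label = lb, window_low_ms = wide[1],
                            window_high_ms = wide[2],
                            n_responses = length(lat), derived = FALSE))
    }
    q <- stats::quantile(lat, c(0.01, 0.99), names = FALSE)
    lo <- max(wide[1], round((q[1] - 0.5) * 2) / 2)
    hi <- min(wide[2], round((q[2] + 0.5) * 2) / 2)
    tibble::tibble(label = lb, window_low_ms = lo, window_high_ms = hi,
                   n_responses = length(lat), derived = TRUE)
  })
  dplyr::bind_rows(out)
}
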