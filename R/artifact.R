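# Stimulation-artifact rejection for facial channels. The post-pulse
# amplifier-recovery artifact (a damped sinusoid persisting up to ~20 ms)
# overlaps the short facial response latencies and shares their frequency
# content, so it cannot be filtered out; it is estimated and subtracted
# instead, always restricted to the 2-20 ms window.

ARTIFACT_WINDOW_MS <- c(2, 20)

#' Build a stimulation-artifact template library
#'
#' Converts a set of pulse-averaged traces known to contain artifact but no
#' evoked response into a reusable template library: each trace is
#' baseline-corrected (baseline median subtracted, microvolt scale),
#' smoothed with a second-order Savitzky-Golay filter (51-sample window at
#' 22 kHz, i.e. about 2.3 ms, rescaled at other rates), cropped to the
#' 2-20 ms artifact window, and stacked; the stack is then augmented with a
#' negated copy of every template so polarity never has to be matched with
#' an absolute value.
#'
#' @param traces A traces tibble from [epoch_average()] or a list of
#'   `averaged_trace` objects.
#' @param window_ms Artifact window, ms (default 2-20).
#' @param sg_window_samples Savitzky-Golay window length; default 51 at
#'   22 kHz, rescaled proportionally at other sampling rates.
#' @return A `template_library`: list with `templates` (matrix
#'   `[n_templates x n_window_samples]`, negation-augmented so the count is
#'   twice the number of input traces), `window_ms`, `fs_hz`, `provenance`.
#' @export
build_template_library <- function(traces, window_ms = ARTIFACT_WINDOW_MS,
                                   sg_window_samples = NULL) {
  if (tibble::is_tibble(traces)) {
    ids <- if ("setting_id" %in% names(traces)) traces$setting_id
           else as.character(seq_len(nrow(traces)))
    traces <- traces$trace
  } else {
    ids <- as.character(seq_along(traces))
  }
  if (length(traces) < 1L) {
    stop_mep("at least one pure-artifact trace is required", "mep_empty_library")
  }
  fs <- traces[[1]]$fs_hz
  if (is.null(sg_window_samples)) {
    sg_window_samples <- odd_at_least_3(51 * fs / 22000)
  }
  n <- length(traces[[1]]$values)
  if (n / fs * 1000 < window_ms[2]) {
    stop_mep("traces shorter than the artifact window", "mep_short_epoch")
  }
  win <- window_idx(n, fs, window_ms)
  rows <- t(vapply(traces, function(tr) {
    v <- tr$values
    v <- v - stats::median(v[baseline_window_idx(length(v))])
    v <- signal::sgolayfilt(v, p = 2, n = sg_window_samples)
    v[win]
  }, numeric(length(win))))
  structure(
    list(
      templates = rbind(rows, -rows),
      window_ms = window_ms,
      fs_hz = fs,
      provenance = c(ids, paste0("neg_", ids))
    ),
    class = "template_library"
  )
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d templates (incl. negations), %g-%g ms @ %g kHz\n",
              nrow(x$templates), x$window_ms[1], x$window_ms[2], x$fs_hz / 1000))
  invisible(x)
}

#' Persist / load a template library
#'
#' The library is stored as a plain CSV matrix (one template per row) next
#' to a JSON header holding the sampling rate, window, and provenance ids.
#'
#' @param lib A `template_library`.
#' @param path CSV path; the JSON header goes to `<path>.json`.
#' @return `read_template_library()` returns the library; the writer returns
#'   `path` invisibly.
#' @export
write_template_library <- function(lib, path) {
  utils::write.table(lib$templates, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(fs_hz = lib$fs_hz, window_ms = lib$window_ms,
         provenance = lib$provenance),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_template_library
#' @export
read_template_library <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(
    list(templates = m, window_ms = hdr$window_ms, fs_hz = hdr$fs_hz,
         provenance = hdr$provenance),
    class = "template_library"
  )
}

# Baseline-median-corrected values of a trace: rejection always fits on the
# baseline-corrected waveform so the slow-drift DC offset of the raw average
# cannot bias the median-scaled amplitude fit (the library templates carry
# no DC either).
baseline_corrected_values <- function(trace) {
  v <- trace$values
  v - stats::median(v[baseline_window_idx(length(v))])
}

# Pearson correlation of one window against every library row.
template_correlations <- function(window_vals, lib) {
  tm <- lib$templates
  wc <- window_vals - mean(window_vals)
  tc <- tm - rowMeans(tm)
  denom <- sqrt(sum(wc^2) * rowSums(tc^2))
  num <- as.numeric(tc %*% wc)
  r <- num / denom
  r[!is.finite(r)] <- -Inf
  r
}

# Subtract a fitted component exactly over the artifact window. The edit is
# deliberately not tapered: the artifact is at its largest right at the 2 ms
# edge, so any edge ramp would leave a residual there proportional to the
# artifact itself, while the step this creates at the window boundary lies
# outside every detection window (facial windows start at 5 ms).
subtract_in_window <- function(values, win, component, fs_hz) {
  values[win] <- values[win] - component
  values
}

#' Template-based artifact rejection
#'
#' Finds the library template whose waveform best matches the trace over
#' the 2-20 ms window (largest Pearson correlation; negated copies are in
#' the library, so no absolute value is taken), fits its amplitude by
#' median-scaling — which a temporally sparse evoked response riding on the
#' artifact barely perturbs — and subtracts the scaled template. The trace
#' is modified only inside the window.
#'
#' @param trace An `averaged_trace` (microvolt scale, before z-scoring).
#' @param lib A `template_library`.
#' @return The trace with the fitted artifact removed; attributes
#'   `"template_index"`, `"template_r"`, and `"template_scale"` record the
#'   decision.
#' @export
template_reject <- function(trace, lib) {
  stopifnot(inherits(trace, "averaged_trace"),
            inherits(lib, "template_library"))
  v <- trace$values
  n <- length(v)
  if (n / trace$fs_hz * 1000 < lib$window_ms[2]) {
    stop_mep("trace shorter than the artifact window", "mep_short_epoch")
  }
  win <- window_idx(n, trace$fs_hz, lib$window_ms)
  if (ncol(lib$templates) != length(win)) {
    stop_mep("library window length does not match the trace sampling",
             "mep_library_mismatch")
  }
  wv <- baseline_corrected_values(trace)[win]
  if (stats::sd(wv) == 0) {
    # constant (e.g. all-zero) window: nothing to match, nothing to remove
    attr(trace, "template_index") <- NA_integer_
    attr(trace, "template_r") <- NA_real_
    attr(trace, "template_scale") <- 0
    return(trace)
  }
  r <- template_correlations(wv, lib)
  best <- which.max(r)
  tmpl <- lib$templates[best, ]
  scale <- median_scale_fit(wv, tmpl)
  trace$values <- subtract_in_window(v, win, scale * tmpl, trace$fs_hz)
  attr(trace, "template_index") <- best
  attr(trace, "template_r") <- r[best]
  attr(trace, "template_scale") <- scale
  trace
}

# Internal PCA rejection on an explicit data matrix [channels x window].
# Returns the per-channel fitted components to subtract. The median-scaled
# fit pairs the raw (baseline-corrected, uncentred) row with PC1 and
# excludes samples where the template falls below 5% of its peak: centring
# the row would smear a sparse response's mean over the whole window, and
# ratios against the template's decayed tail are dominated by whatever
# rides on top of it — both systematically bias the ratio median.
pca_components <- function(X, scaling) {
  Xc <- X - rowMeans(X)
  sv <- svd(Xc)
  v1 <- sv$v[, 1]
  d1 <- sv$d[1]
  u1 <- sv$u[, 1]
  t(vapply(seq_len(nrow(X)), function(i) {
    switch(scaling,
      remove_pc1 = u1[i] * d1 * v1,
      euclidean_fit = as.numeric(crossprod(Xc[i, ], v1)) * v1,
      median_scaling = median_scale_fit(X[i, ], v1, eps = 0.05) * v1
    )
  }, numeric(length(v1))))
}

#' PCA-based artifact rejection
#'
#' Exploits the observation that the recovery artifact takes a similar
#' shape across facial channels while evoked responses differ in latency
#' and shape between muscles: the first principal component of the
#' cross-channel data matrix over the 2-20 ms window serves as a
#' data-driven artifact template, scaled and subtracted per channel.
#'
#' @param traces A traces tibble (see [epoch_average()]).
#' @param channel_subset Which channels form the PCA basis: facial channels
#'   only (default, the best-performing choice), all EMG channels, or EMG
#'   plus caller-supplied extra channels (e.g. concurrent LFP traces).
#' @param scaling How the PC1 template is scaled per channel before
#'   subtraction: `"median_scaling"` (default; least influenced by an
#'   overlapping evoked response), `"euclidean_fit"` (least-squares
#'   projection), or `"remove_pc1"` (full removal of each channel's PC1
#'   contribution, which can also remove part of a large response).
#' @param extra_channels Optional numeric matrix of additional basis rows
#'   (already restricted to the full epoch length).
#' @param window_ms Artifact window, ms.
#' @return The traces tibble with facial traces cleaned. If fewer than two
#'   usable channels are available the input is returned unchanged with
#'   attribute `"pca_skipped" = TRUE` and a warning.
#' @export
pca_reject <- function(traces,
                       channel_subset = c("facial_only", "all_emg",
                                          "emg_plus_lfp"),
                       scaling = c("median_scaling", "remove_pc1",
                                   "euclidean_fit"),
                       extra_channels = NULL,
                       window_ms = ARTIFACT_WINDOW_MS) {
  channel_subset <- match.arg(channel_subset)
  scaling <- match.arg(scaling)
  basis_rows <- switch(channel_subset,
    facial_only = which(traces$group == "facial"),
    all_emg = seq_len(nrow(traces)),
    emg_plus_lfp = seq_len(nrow(traces))
  )
  target_rows <- which(traces$group == "facial")
  fs <- traces$trace[[1]]$fs_hz
  n <- length(traces$trace[[1]]$values)
  win <- window_idx(n, fs, window_ms)
  X <- t(vapply(traces$trace[basis_rows],
                function(tr) baseline_corrected_values(tr)[win],
                numeric(length(win))))
  if (channel_subset == "emg_plus_lfp" && !is.null(extra_channels)) {
    X <- rbind(X, extra_channels[, win, drop = FALSE])
  }
  if (nrow(X) < 2L || length(target_rows) == 0L) {
    warning("pca_reject: fewer than 2 usable channels; traces unchanged")
    attr(traces, "pca_skipped") <- TRUE
    return(traces)
  }
  comp_basis <- pca_components(X, scaling)
  # components for target channels: rows of the basis matrix when present,
  # otherwise fit PC1 (recomputed) to the target directly
  sv1 <- svd(X - rowMeans(X))$v[, 1]
  for (tr_i in target_rows) {
    pos <- match(tr_i, basis_rows)
    tv <- baseline_corrected_values(traces$trace[[tr_i]])[win]
    comp <- if (!is.na(pos)) {
      comp_basis[pos, ]
    } else {
      median_scale_fit(tv, sv1, eps = 0.05) * sv1
    }
    # the zero-mean PC1 cannot carry the artifact's own window mean; add it
    # back as a robust offset (the median ignores a sparse evoked response)
    comp <- comp + stats::median(tv - comp)
    traces$trace[[tr_i]]$values <- subtract_in_window(
      traces$trace[[tr_i]]$values, win, comp, fs
    )
  }
  traces
}

#' Template-PCA hybrid artifact rejection
#'
#' Combines the trial-specific, data-driven estimation of [pca_reject()]
#' with the overfitting resistance of [template_reject()]: the library
#' template best matching the facial channels (largest mean Pearson
#' correlation over the artifact window) is appended to the facial data
#' matrix — replicated until the row count doubles — before PCA, anchoring
#' the first principal component to a known artifact shape. The fitted
#' component is subtracted only from the original channels.
#'
#' @inheritParams pca_reject
#' @param lib A `template_library`.
#' @param scaling Per-channel scaling method (as [pca_reject()]).
#' @return The traces tibble with facial traces cleaned.
#' @export
template_pca_reject <- function(traces, lib,
                                scaling = c("median_scaling", "remove_pc1",
                                            "euclidean_fit"),
                                window_ms = ARTIFACT_WINDOW_MS) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(lib, "template_library"))
  facial <- which(traces$group == "facial")
  if (length(facial) == 0L) return(traces)
  fs <- traces$trace[[1]]$fs_hz
  n <- length(traces$trace[[1]]$values)
  win <- window_idx(n, fs, window_ms)
  if (ncol(lib$templates) != length(win)) {
    stop_mep("library window length does not match the trace sampling",
             "mep_library_mismatch")
  }
  F <- t(vapply(traces$trace[facial],
                function(tr) baseline_corrected_values(tr)[win],
                numeric(length(win))))
  r_mat <- vapply(seq_len(nrow(F)), function(i) {
    template_correlations(F[i, ], lib)
  }, numeric(nrow(lib$templates)))
  best <- which.max(rowMeans(r_mat))
  aug <- matrix(rep(lib$templates[best, ], nrow(F)), nrow = nrow(F),
                byrow = TRUE)
  X <- rbind(F, aug)                  # doubled row count
  comp <- pca_components(X, scaling)
  for (j in seq_along(facial)) {
    i <- facial[j]
    cj <- comp[j, ] + stats::median(F[j, ] - comp[j, ])
    traces$trace[[i]]$values <- subtract_in_window(
      traces$trace[[i]]$values, win, cj, fs
    )
  }
  attr(traces, "template_index") <- best
  traces
}
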