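#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a setting score
#'
#' One row per channel with the detection outcome and normalized amplitude.
#'
#' @param x A `setting_score`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy setting_score
#' @export
tidy.setting_score <- function(x, ...) {
  x$detections
}

#' One-row summary of a setting score
#'
#' @param x A `setting_score`.
#' @param ... Unused.
#' @return A one-row tibble (`mep_score`, `n_included`, `n_responding`,
#'   `n_channels`).
#' @method glance setting_score
#' @export
glance.setting_score <- function(x, ...) {
  tibble::tibble(
    mep_score = x$mep_score,
    n_included = x$n_included,
    n_responding = x$n_responding,
    n_channels = nrow(x$detections)
  )
}

#' Tidy a normalization table
#'
#' @param x A `normalization_table`.
#' @param ... Unused.
#' @return The underlying tibble plus a `pooled_iqr` column.
#' @method tidy normalization_table
#' @export
tidy.normalization_table <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$pooled_iqr <- attr(x, "pooled_iqr")
  out
}

#' Convert a trace to a tibble
#'
#' @param x An `averaged_trace` or `zscored_trace`.
#' @param ... Unused.
#' @return Tibble with `time_ms`, `value`, `label`.
#' @importFrom tibble as_tibble
#' @method as_tibble averaged_trace
#' @export
as_tibble.averaged_trace <- function(x, ...) {
  tibble::tibble(
    time_ms = epoch_time_ms(length(x$values), x$fs_hz),
    value = x$values,
    label = x$channel$label
  )
}

#' @rdname as_tibble.averaged_trace
#' @method as_tibble zscored_trace
#' @export
as_tibble.zscored_trace <- as_tibble.averaged_trace
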