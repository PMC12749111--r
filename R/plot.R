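# ggplot2 displays for traces and scores.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pulse-averaged trace
#'
#' @param object An `averaged_trace`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot averaged_trace
#' @export
autoplot.averaged_trace <- function(object, ...) {
  df <- as_tibble.averaged_trace(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time after pulse (ms)", y = "Amplitude (µV)",
                  title = object$channel$label) +
    ggplot2::theme_minimal()
}

#' Plot a z-scored trace with its detection window and threshold
#'
#' @param object A `zscored_trace`.
#' @param cfg A [detection_config()] (for the window and threshold bands).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot zscored_trace
#' @export
autoplot.zscored_trace <- function(object, cfg = detection_config(), ...) {
  df <- as_tibble.averaged_trace(object)
  mu <- object$channel
  win <- muscle_window(mu$label, mu$group, cfg)
  thr <- group_threshold(mu$group, cfg)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::annotate("rect", xmin = win[1], xmax = win[2],
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_hline(yintercept = c(-thr, thr), linetype = "dashed",
                        colour = "firebrick", linewidth = 0.3) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time after pulse (ms)", y = "Amplitude (z)",
                  title = mu$label) +
    ggplot2::theme_minimal()
}

#' Plot per-channel contributions to a setting score
#'
#' Bars of normalized response amplitudes per muscle, coloured by detection
#' status, with the setting's mEP score in the title.
#'
#' @param object A `setting_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot setting_score
#' @export
autoplot.setting_score <- function(object, ...) {
  d <- object$detections
  d$normalized_amplitude[is.na(d$normalized_amplitude)] <- 0
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label,
                                  y = .data$normalized_amplitude,
                                  fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(response = "#2166ac",
                                          no_response = "grey60",
                                          excluded = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "Normalized amplitude",
                  title = sprintf("mEP score %.2f", object$mep_score)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot mEP score vs stimulation amplitude
#'
#' Recruitment-curve style display of per-setting scores, one panel per
#' contact configuration.
#'
#' @param scores Scores tibble from [process_corpus()].
#' @return A ggplot.
#' @export
plot_recruitment <- function(scores) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$amplitude_ma,
                                       y = .data$mep_score)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~contact_config) +
    ggplot2::labs(x = "Stimulation amplitude (mA)", y = "mEP score") +
    ggplot2::theme_minimal()
}
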