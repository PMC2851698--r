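#' Plot the channels of a recording
#'
#' Facetted trace of the EDA, respiration and BVP channels with annotated
#' event stimulus times marked.
#'
#' @param object An [recording()].
#' @param channels Which channels to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot edr_recording
#' @export
autoplot.edr_recording <- function(object,
                                   channels = c("eda", "resp", "bvp"), ...) {
  df <- tidyr::pivot_longer(as_tibble(object)[c("time", channels)],
                            -"time", names_to = "channel")
  df$channel <- factor(df$channel, levels = channels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  ann <- annotations(object)
  if (nrow(ann) > 0L) {
    p <- p + ggplot2::geom_vline(
      data = tibble(onset_s = ann$onset_s, kind = ann$kind),
      ggplot2::aes(xintercept = .data$onset_s, colour = .data$kind),
      linetype = "dashed", alpha = 0.6) +
      ggplot2::labs(colour = "event")
  }
  p
}

#' Plot classified EDRs over the EDA trace
#'
#' @param rec The classified [recording()].
#' @param events Classified events from [classify_edr()].
#' @return A ggplot of the EDA trace with detection onsets coloured by
#'   predicted label.
#' @export
plot_classification <- function(rec, events) {
  ggplot2::ggplot(as_tibble(rec), ggplot2::aes(x = .data$time, y = .data$eda)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = events,
                        ggplot2::aes(xintercept = .data$onset_s,
                                     colour = .data$predicted_label)) +
    ggplot2::scale_colour_manual(values = c(voluntary = "firebrick",
                                            involuntary = "dodgerblue3"),
                                 na.value = "grey60") +
    ggplot2::labs(x = "time (s)", y = "EDA (uS)", colour = "predicted") +
    ggplot2::theme_minimal()
}
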