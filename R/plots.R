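# ggplot2 graphics for the result objects.

#' Spectrogram heat map
#'
#' @param object A [multitaper_spectrogram()] result.
#' @param channel Channel id or index to plot (default first).
#' @param f_max Upper frequency limit in Hz.
#' @param ... Unused.
#' @return A ggplot object (time x frequency, fill = power in dB).
#' @method autoplot spectral_estimate
#' @export
autoplot.spectral_estimate <- function(object, channel = 1, f_max = 100,
                                       ...) {
  if (is.numeric(channel)) channel <- object$channel_ids[channel]
  df <- tidy(object) |>
    dplyr::filter(.data$channel == !!channel, .data$freq <= f_max) |>
    dplyr::mutate(db = 10 * log10(pmax(.data$power, 1e-30)))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$freq,
                                   fill = .data$db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power (dB)") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", title = channel) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of ROI band-power changes
#'
#' Mean dB change with bootstrap CI per ROI, faceted by band and contrast;
#' grey marks intervals overlapping zero (no change), matching the usual
#' presentation of this analysis.
#'
#' @param object A [roi_summarize()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roi_summary
#' @export
autoplot.roi_summary <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$roi,
                                   colour = .data$classification)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::scale_colour_manual(values = c(increase = "#c0392b",
                                            decrease = "#2980b9",
                                            no_change = "grey55")) +
    ggplot2::facet_grid(band ~ contrast) +
    ggplot2::labs(x = "power change (dB)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Contrast spectrum with bootstrap ribbon
#'
#' @param spectrum A [roi_spectrum()] tibble.
#' @param f_max Upper frequency limit in Hz.
#' @return A ggplot object (mean dB difference vs frequency with CI
#'   ribbon).
#' @export
plot_roi_spectrum <- function(spectrum, f_max = 55) {
  df <- dplyr::filter(spectrum, .data$freq <= f_max)
  ggplot2::ggplot(df, ggplot2::aes(.data$freq, .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo,
                                      ymax = .data$ci_hi),
                         fill = "grey75", alpha = 0.6) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "frequency (Hz)", y = "power change (dB)") +
    ggplot2::theme_minimal()
}
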