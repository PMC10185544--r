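#' Plot an averaged SSEP waveform
#'
#' Line plot of the ERP in microvolts against post-stimulus time, with the
#' extracted maximal positive peak marked.
#'
#' @param object A `ssep_erp` from [compute_erp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssep_erp
#' @export
autoplot.ssep_erp <- function(object, ...) {
  peak <- extract_amplitude_latency(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ms, y = .data$amplitude_uv)) +
    ggplot2::geom_line(colour = "grey25") +
    ggplot2::geom_vline(xintercept = peak$latency_ms, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "time post-stimulus (ms)", y = "amplitude (µV)",
      title = sprintf("%s / %s ERP", attr(object, "patient_id"),
                      attr(object, "side")),
      subtitle = sprintf("peak-to-peak %.2f µV, latency %.1f ms",
                         peak$amplitude_uv, peak$latency_ms)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a spectrogram with its TFA region
#'
#' Tile heat map of spectral power with the fixed integration region
#' outlined.
#'
#' @param object A `ssep_spectrogram` from [compute_tfa_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssep_spectrogram
#' @export
autoplot.ssep_spectrogram <- function(object, ...) {
  # power is freq x time; as.vector is column-major (freq fastest)
  df <- tibble::tibble(
    freq_hz = rep(object$freq_hz, times = length(object$time_ms)),
    time_ms = rep(object$time_ms, each = length(object$freq_hz)),
    power = as.vector(object$power)
  )
  reg <- object$region
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$freq_hz,
                                   fill = .data$power)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("rect",
                      xmin = reg$time_ms[1], xmax = reg$time_ms[2],
                      ymin = reg$freq_hz[1], ymax = reg$freq_hz[2],
                      colour = "white", fill = NA, linewidth = 0.4) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time post-stimulus (ms)", y = "frequency (Hz)",
                  fill = "power") +
    ggplot2::theme_minimal()
}

#' Plot the per-grade abnormality-category distribution
#'
#' Stacked bar chart of the category percentages (no abnormality /
#' amplitude only / amplitude + power / power only) within each MRI grade —
#' the patient-distribution view used to speculate compression progression.
#'
#' @param object A `ssep_report` from [run_pipeline()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssep_report
#' @export
autoplot.ssep_report <- function(object, ...) {
  cd <- object$category_distribution
  long <- cd |>
    dplyr::filter(!.data$empty) |>
    tidyr::pivot_longer(
      dplyr::all_of(c("pct_no_abnormality", "pct_amp_only",
                      "pct_amp_power", "pct_power_only")),
      names_to = "category", values_to = "pct"
    ) |>
    dplyr::mutate(category = factor(
      .data$category,
      levels = c("pct_no_abnormality", "pct_amp_only", "pct_amp_power",
                 "pct_power_only"),
      labels = c("no abnormality", "amplitude only", "amplitude + power",
                 "power only")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$grade), y = .data$pct,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1) +
    ggplot2::labs(x = "MRI compression grade", y = "patients (%)",
                  fill = "SSEP change",
                  title = "Abnormality categories by compression grade") +
    ggplot2::theme_minimal()
}
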