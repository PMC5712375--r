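#' Plot a time-frequency spectrum
#'
#' Heat map of the energy grid (Hilbert or Stockwell), with time on the
#' x axis and frequency on the y axis.
#'
#' @param object A `tf_spectrum`.
#' @param max_freq_hz Crop the frequency axis (default 60 Hz, which
#'   covers the analysis bands).
#' @param log10_energy Plot `log10(energy + eps)` for visibility
#'   (default TRUE).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tf_spectrum
#' @export
autoplot.tf_spectrum <- function(object, max_freq_hz = 60,
                                 log10_energy = TRUE, ...) {
  sel <- object$freq_hz <= max_freq_hz
  df <- tidyr::expand_grid(freq_hz = object$freq_hz[sel],
                           t_s = (seq_len(ncol(object$grid)) - 1) / object$fs)
  df$energy <- as.vector(object$grid[sel, , drop = FALSE])
  if (log10_energy) df$energy <- log10(df$energy + 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$freq_hz,
                                   fill = .data$energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (log10_energy) "log10 energy" else "energy") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot per-trial indices of a pipeline run
#'
#' Weighted Discriminator per evaluated trial, with the run mean as a
#' dashed line.
#'
#' @param object A `bci_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bci_run
#' @export
autoplot.bci_run <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$trial), .data$wd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$summary$wd,
                        linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(-1, 1)) +
    ggplot2::labs(x = "test trial", y = "Weighted Discriminator",
                  title = sprintf("%s / %s model / %s", object$method,
                                  object$event, object$protocol)) +
    ggplot2::theme_minimal()
}

#' Plot one channel of a trial with its events
#'
#' @param trial An `eeg_trial`.
#' @param channel Channel name (default the first).
#' @return A ggplot object.
#' @export
plot_trial_channel <- function(trial, channel = trial$channel_names[1]) {
  stopifnot(channel %in% trial$channel_names)
  n <- ncol(trial$data)
  df <- tibble::tibble(t_s = (seq_len(n) - 1) / trial$sample_rate,
                       uv = trial$data[channel, ])
  ggplot2::ggplot(df, ggplot2::aes(.data$t_s, .data$uv)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::geom_vline(data = trial$events,
                        ggplot2::aes(xintercept = .data$time_s,
                                     colour = .data$kind),
                        linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = sprintf("%s (uV)", channel),
                  colour = "event") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
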