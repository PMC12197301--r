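# ggplot2 views of the main result types.

#' Plot a waveform with detected segments
#'
#' @param clip An [audio_clip()].
#' @param segments Optional segment tibble from [detect_segments()].
#' @param downsample Plot every k-th sample (default keeps ~20k points).
#' @return A ggplot object.
#' @export
plot_segments <- function(clip, segments = NULL, downsample = NULL) {
  stopifnot(inherits(clip, "audio_clip"))
  k <- downsample %||% max(1L, length(clip$samples) %/% 20000L)
  ix <- seq(1, length(clip$samples), by = k)
  df <- tibble(time_s = (ix - 1) / clip$sample_rate_hz,
               amplitude = clip$samples[ix])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude")
  if (!is.null(segments) && nrow(segments)) {
    p <- p + ggplot2::geom_rect(
      data = segments,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "orange", alpha = 0.25)
  }
  p
}

#' @export
autoplot.stft_spec <- function(object, ...) {
  df <- tidyr::expand_grid(frame = seq_along(object$time_s),
                           bin = seq_along(object$freq_hz)) |>
    arrange(.data$frame, .data$bin)
  df$power <- log1p(as.vector(object$magnitude))
  df$time_s <- object$time_s[df$frame]
  df$freq_hz <- object$freq_hz[df$bin]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$freq_hz,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "log(1+|S|)")
}

#' @export
autoplot.cwt_scalogram <- function(object, ...) {
  n_t <- ncol(object$magnitude)
  df <- tidyr::expand_grid(scale_ix = seq_along(object$scales),
                           t_ix = seq_len(n_t)) |>
    arrange(.data$scale_ix, .data$t_ix)
  df$power <- log1p(as.vector(t(object$magnitude)))
  df$time_s <- (df$t_ix - 1) / object$sample_rate_hz
  df$pseudo_freq_hz <- object$pseudo_freq_hz[df$scale_ix]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$pseudo_freq_hz,
                                   fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "pseudo-frequency (Hz)",
                  fill = "log(1+|W|)")
}

#' @export
autoplot.saliva_eval <- function(object, ...) {
  lims <- range(c(object$trials$saliva_g, object$trials$.pred))
  ggplot2::ggplot(object$trials,
                  ggplot2::aes(.data$saliva_g, .data$.pred)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::coord_equal(xlim = lims, ylim = lims) +
    ggplot2::labs(x = "measured saliva (g / 30 s)",
                  y = "estimated saliva (g / 30 s)",
                  title = sprintf("LOOCV: r = %.3f, MAE = %.4f g",
                                  object$metrics$r, object$metrics$mae))
}

#' MAE curve over the measured secretion range
#'
#' @param eval A `saliva_eval` object.
#' @param target_g Reference accuracy line in grams (default 0.07, the
#'   stated usefulness threshold).
#' @return A ggplot object.
#' @export
plot_mae_curve <- function(eval, target_g = 0.07) {
  stopifnot(inherits(eval, "saliva_eval"))
  ggplot2::ggplot(eval$mae_curve,
                  ggplot2::aes(.data$bin_center_g, .data$mae_g)) +
    ggplot2::geom_hline(yintercept = target_g, linetype = 2,
                        colour = "red") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::labs(x = "measured saliva (g / 30 s)", y = "MAE (g)",
                  size = "trials")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
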