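#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures: the raw recording with
#' annotated beats, the integrated spectrum, the per-epoch training loss of
#' the autoencoder, and the refined heart-rate trace colored by quality.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name fetalhr_autoplot
NULL

#' @rdname fetalhr_autoplot
#' @param max_points Downsample the trace to at most this many points for
#'   display (default 20000).
#' @export
autoplot.dus_recording <- function(object, max_points = 20000L, ...) {
  df <- as_tibble(object)
  if (nrow(df) > max_points) {
    df <- df[unique(round(seq(1L, nrow(df), length.out = max_points))), ]
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)")
  sched <- attr(object, "schedule")
  if (!is.null(sched)) {
    p <- p + ggplot2::geom_vline(xintercept = sched$beat_time,
                                 colour = "red", alpha = 0.25,
                                 linewidth = 0.2)
  }
  p
}

#' @rdname fetalhr_autoplot
#' @export
autoplot.integrated_spectrum <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$power)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "integrated band power (a.u.)")
}

#' @rdname fetalhr_autoplot
#' @export
autoplot.dus_vae <- function(object, ...) {
  df <- tidyr::pivot_longer(object$log, -"epoch",
                            names_to = "term", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training loss")
}

#' @rdname fetalhr_autoplot
#' @export
autoplot.refined_trace <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      fhr_raw = 60 / .data$frri_raw,
                      fhr_refined = 60 / .data$frri_kf2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fhr_raw), size = 0.4,
                        colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fhr_refined,
                                    alpha = .data$kept),
                       colour = "firebrick") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.2),
                                guide = "none") +
    ggplot2::labs(x = "time (s)", y = "fetal heart rate (bpm)")
}
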