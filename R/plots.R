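# ggplot2 graphics for the main result types.

#' Plot a vertical signal with detected gait events
#'
#' @param object A `vertical_signal`.
#' @param events Optional `gait_events` tibble to overlay.
#' @param window Optional length-2 time window (s) to restrict the plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.vertical_signal <- function(object, events = NULL, window = NULL,
                                     ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(window)) {
    df <- dplyr::filter(df, .data$time >= window[1], .data$time <= window[2])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$a_v)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = expression(a[v] ~ (m / s^2)))
  if (!is.null(events)) {
    ev <- tibble::as_tibble(events)
    if (!is.null(window)) {
      ev <- dplyr::filter(ev, .data$t >= window[1], .data$t <= window[2])
    }
    p <- p + ggplot2::geom_vline(
      data = ev,
      ggplot2::aes(xintercept = .data$t, colour = .data$kind),
      linetype = "dashed", alpha = 0.6
    ) +
      ggplot2::labs(colour = "event")
  }
  p
}

#' Bland-Altman plot of two paired measurement series
#'
#' Differences against means with the mean difference and 95% limits of
#' agreement.
#'
#' @param x,y Paired series.
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(x, y, xlab = "mean of methods",
                              ylab = "difference (x - y)") {
  ba <- bland_altman(x, y)
  df <- tibble::tibble(m = (x + y) / 2, d = x - y)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_diff, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", colour = "steelblue") +
    ggplot2::labs(x = xlab, y = ylab)
}

#' Held-out predicted score against the clinician score
#'
#' @param object A `gait_model_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.gait_model_eval <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = factor(.data$observed),
                               y = .data$predicted)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "clinician gait score",
                  y = "predicted score (leave-one-subject-out)")
}
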