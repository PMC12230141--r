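#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an averaged response
#'
#' Waveform with the N1/P2 search windows and the signal / noise-floor RMS
#' windows shaded, plus the tone onset marker.
#'
#' @param object an `acc_average` (see [average_epochs()]).
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot acc_average
#' @export
autoplot.acc_average <- function(object, ...) {
  if (object$inconclusive) stop("nothing to plot: inconclusive average", call. = FALSE)
  d <- object$design
  df <- tibble::tibble(time_s = d$time_s, uv = object$waveform)
  shade <- tibble::tibble(
    window = factor(c("N1", "P2", "noise floor"),
                    levels = c("N1", "P2", "noise floor")),
    xmin = c(d$n1_window_s[1], d$p2_window_s[1], d$rms_noise_window_s[1]),
    xmax = c(d$n1_window_s[2], d$p2_window_s[2], d$rms_noise_window_s[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$uv)) +
    ggplot2::geom_rect(data = shade, inherit.aes = FALSE,
                       ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = -Inf, ymax = Inf,
                                    fill = .data$window), alpha = 0.15) +
    ggplot2::geom_vline(xintercept = d$tone_onset_s, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time re masker onset (s)", y = "amplitude (µV)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot
#'
#' Differences against pair means with the bias (dashed) and the 95% limits
#' of agreement (dot-dash).
#'
#' @param object an `acc_agreement` from [bland_altman()] or
#'   [repeatability()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot acc_agreement
#' @export
autoplot.acc_agreement <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, difference = object$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(object$loa_lower, object$loa_upper),
                        linetype = "dotdash") +
    ggplot2::labs(x = "mean of pair", y = "difference") +
    ggplot2::theme_minimal()
}
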