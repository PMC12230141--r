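#' Deterministic ACC waveform template
#'
#' Biphasic N1-P2 morphology used to embed a response in synthetic epochs: a
#' negative Gaussian-windowed deflection centred at the N1 latency and a
#' positive one at the P2 latency. The waveform is identically zero outside
#' `[tone_onset_s, tone_onset_s + 0.4]` s; its most negative sample sits at
#' the N1 latency and its most positive at the P2 latency, and the
#' peak-to-peak amplitude equals `n1_amp_uv + p2_amp_uv` (the component
#' Gaussians are far enough apart that their overlap is negligible).
#'
#' @param design an [acc_design()].
#' @param n1_amp_uv,p2_amp_uv deflection magnitudes in uV (both given as
#'   positive numbers; the N1 deflection is applied negatively).
#' @param n1_lat_s,p2_lat_s peak latencies in seconds; must fall inside the
#'   design's N1/P2 windows.
#' @param n1_width_s,p2_width_s full width at half maximum of each
#'   deflection, seconds.
#' @return Numeric vector of length `design$n_samples`, in uV.
#' @examples
#' d <- acc_design(fs = 256)
#' w <- acc_template(d, n1_amp_uv = 3, p2_amp_uv = 2)
#' max(w) - min(w)  # ~5
#' @export
acc_template <- function(design, n1_amp_uv = 3, p2_amp_uv = 2,
                         n1_lat_s = 1.100, p2_lat_s = 1.200,
                         n1_width_s = 0.030, p2_width_s = 0.050) {
  validate_design(design)
  if (n1_lat_s < design$n1_window_s[1] || n1_lat_s > design$n1_window_s[2]) {
    stop("n1_lat_s outside the design N1 window", call. = FALSE)
  }
  if (p2_lat_s < design$p2_window_s[1] || p2_lat_s > design$p2_window_s[2]) {
    stop("p2_lat_s outside the design P2 window", call. = FALSE)
  }
  if (n1_amp_uv < 0 || p2_amp_uv < 0) stop("amplitudes must be >= 0", call. = FALSE)
  t <- design$time_s
  # FWHM -> Gaussian sigma
  s1 <- n1_width_s / (2 * sqrt(2 * log(2)))
  s2 <- p2_width_s / (2 * sqrt(2 * log(2)))
  w <- -n1_amp_uv * exp(-(t - n1_lat_s)^2 / (2 * s1^2)) +
    p2_amp_uv * exp(-(t - p2_lat_s)^2 / (2 * s2^2))
  w[t < design$tone_onset_s | t > design$tone_onset_s + 0.4] <- 0
  w
}
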