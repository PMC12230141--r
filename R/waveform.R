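#' Measure N1 and P2 peaks on an averaged response
#'
#' N1 is the most negative sample within the design's N1 window and P2 the
#' most positive sample within the P2 window; ties are broken by the
#' earliest sample and latencies are reported at sample centres. Peaks are
#' raw extrema (no interpolation) unless `interpolate = TRUE`, which refines
#' each latency/amplitude by a parabolic fit through the extremum and its
#' two neighbours.
#'
#' @param avg an `acc_average` (see [average_epochs()]) or a bare numeric
#'   waveform of length `design$n_samples`.
#' @param design an [acc_design()]; taken from `avg` when omitted.
#' @param interpolate parabolic peak interpolation flag (default off).
#' @return A one-row tibble: `n1_latency_s`, `n1_amp_uv` (signed),
#'   `p2_latency_s`, `p2_amp_uv` (signed), and the peak-to-peak
#'   `n1p2_amp_uv = p2_amp_uv - n1_amp_uv`.
#' @examples
#' d <- acc_design(fs = 256)
#' w <- acc_template(d, 3, 2)
#' find_peaks(w, d)
#' @export
find_peaks <- function(avg, design = NULL, interpolate = FALSE) {
  if (inherits(avg, "acc_average")) {
    if (avg$inconclusive) stop("averaged response is inconclusive", call. = FALSE)
    design <- avg$design
    w <- avg$waveform
  } else {
    if (is.null(design)) stop("design required for a bare waveform", call. = FALSE)
    w <- as.numeric(avg)
  }
  validate_design(design)
  if (length(w) != design$n_samples) {
    stop("waveform length does not match the design", call. = FALSE)
  }
  pick <- function(window_s, which_fun) {
    idx <- window_idx(design, window_s)
    v <- w[idx]
    j <- idx[which_fun(v)]  # which.min/which.max take the first on ties
    amp <- w[j]
    lat <- design$time_s[j]
    if (interpolate && j > 1 && j < length(w)) {
      y1 <- w[j - 1]; y2 <- w[j]; y3 <- w[j + 1]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > .Machine$double.eps) {
        delta <- 0.5 * (y1 - y3) / denom
        if (abs(delta) <= 1) {
          lat <- lat + delta / design$fs
          amp <- y2 - 0.25 * (y1 - y3) * delta
        }
      }
    }
    c(lat = lat, amp = amp)
  }
  n1 <- pick(design$n1_window_s, which.min)
  p2 <- pick(design$p2_window_s, which.max)
  tibble::tibble(
    n1_latency_s = n1[["lat"]], n1_amp_uv = n1[["amp"]],
    p2_latency_s = p2[["lat"]], p2_amp_uv = p2[["amp"]],
    n1p2_amp_uv = p2[["amp"]] - n1[["amp"]]
  )
}

#' RMS over a time window of an averaged response
#'
#' Root mean square of the samples in the half-open window
#' `[window_s[1], window_s[2])`.
#'
#' @param avg an `acc_average` or bare numeric waveform.
#' @param window_s `(start, end)` in seconds on the epoch time axis.
#' @param design an [acc_design()]; taken from `avg` when omitted.
#' @return RMS in uV (scalar).
#' @examples
#' d <- acc_design(fs = 256)
#' segment_rms(rep(2, d$n_samples), c(1.08, 1.23), d)  # 2
#' @export
segment_rms <- function(avg, window_s, design = NULL) {
  if (inherits(avg, "acc_average")) {
    if (avg$inconclusive) stop("averaged response is inconclusive", call. = FALSE)
    design <- avg$design
    w <- avg$waveform
  } else {
    if (is.null(design)) stop("design required for a bare waveform", call. = FALSE)
    w <- as.numeric(avg)
  }
  validate_design(design)
  idx <- window_idx(design, window_s)
  sqrt(mean(w[idx]^2))
}
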