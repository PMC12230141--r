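#' Epoched EEG container
#'
#' An `acc_epochs` object holds one recording's epoched EEG for a single
#' condition and channel: an `n_epochs x n_samples` matrix in uV, the design
#' it was cut against, the condition labels, per-epoch acceptance flags, and
#' the seed used if the data are synthetic.
#'
#' @param data numeric matrix, `n_epochs x n_samples`, uV.
#' @param design the [acc_design()] the epochs follow.
#' @param channel_role `"ipsi"` or `"contra"` mastoid.
#' @param condition named list or vector with `frequency_hz`, `snr_db`,
#'   `repetition`.
#' @param accepted logical vector, one flag per epoch (default all `TRUE`).
#' @param seed integer seed used to generate the data, or `NA`.
#' @return An object of class `acc_epochs`.
#' @export
acc_epochs <- function(data, design, channel_role = c("ipsi", "contra"),
                       condition = list(frequency_hz = NA_real_,
                                        snr_db = NA_real_, repetition = 1L),
                       accepted = rep(TRUE, nrow(data)),
                       seed = NA_integer_) {
  channel_role <- match.arg(channel_role)
  validate_design(design)
  data <- as.matrix(data)
  if (ncol(data) != design$n_samples) {
    stop("epochs have ", ncol(data), " samples but the design implies ",
         design$n_samples, call. = FALSE)
  }
  if (nrow(data) > design$sweeps) {
    stop("more epochs (", nrow(data), ") than design sweeps (",
         design$sweeps, ")", call. = FALSE)
  }
  stopifnot(length(accepted) == nrow(data), is.logical(accepted))
  structure(list(
    data = data,
    design = design,
    channel_role = channel_role,
    condition = as.list(condition),
    accepted = accepted,
    seed = seed
  ), class = "acc_epochs")
}

#' @export
print.acc_epochs <- function(x, ...) {
  cat(sprintf("<acc_epochs> %d epochs x %d samples (%s), %d accepted\n",
              nrow(x$data), ncol(x$data), x$channel_role, sum(x$accepted)))
  cond <- x$condition
  cat(sprintf("  condition: %s Hz, %s dB SNR, repetition %s\n",
              format(cond$frequency_hz), format(cond$snr_db),
              format(cond$repetition)))
  invisible(x)
}

#' @export
dim.acc_epochs <- function(x) dim(x$data)

# 1/f-shaped band-limited Gaussian noise, one epoch per row, scaled so each
# epoch has the requested RMS. Spectral amplitude ~ f^(-1/2) within
# [band[1], band[2]] Hz, zero outside (plus an optional alpha bump at 10 Hz).
shaped_noise <- function(n_epochs, n_samples, fs, rms_uv,
                         band = c(1, 30), alpha_weight = 0.3) {
  if (rms_uv <= 0) return(matrix(0, n_epochs, n_samples))
  freqs <- seq(0, fs / 2, length.out = floor(n_samples / 2) + 1)
  shape <- ifelse(freqs >= band[1] & freqs <= band[2], 1 / sqrt(pmax(freqs, band[1])), 0)
  if (alpha_weight > 0) {
    shape <- shape + alpha_weight * exp(-(freqs - 10)^2 / (2 * 1.5^2)) / sqrt(10)
  }
  out <- matrix(0, n_epochs, n_samples)
  for (i in seq_len(n_epochs)) {
    white <- stats::rnorm(n_samples)
    spec <- stats::fft(white)
    full_shape <- numeric(n_samples)
    full_shape[seq_along(freqs)] <- shape
    if (n_samples > 1) {
      tail_idx <- seq(length(freqs) + 1, n_samples)
      full_shape[tail_idx] <- rev(shape[2:(n_samples - length(freqs) + 1)])
    }
    x <- Re(stats::fft(spec * full_shape, inverse = TRUE)) / n_samples
    sd_x <- stats::sd(x)
    out[i, ] <- if (sd_x > 0) x * (rms_uv / sd_x) else x
  }
  out
}

#' Simulate epoched EEG for one recording
#'
#' Generates `design$sweeps` epochs of band-limited 1/f-shaped background EEG
#' with an ACC template embedded at the amplitude implied by the
#' participant's profile for the given condition and channel. Each epoch's
#' template is jittered in latency by a Gaussian draw
#' (`profile$latency_jitter_ms`); a fraction `profile$artifact_rate` of
#' epochs is replaced by 10x-amplitude noise bursts (the artifacts the
#' rejection stage must catch). Fixed `seed` gives bit-identical output.
#'
#' @param design an [acc_design()].
#' @param profile a [participant_profile()].
#' @param condition list with `frequency_hz`, `snr_db`, `repetition`.
#' @param channel_role `"ipsi"` or `"contra"`.
#' @param seed integer seed.
#' @return An [acc_epochs()] object (all epochs flagged accepted; rejection
#'   is a preprocessing decision).
#' @examples
#' d <- acc_design(fs = 256, sweeps = 20)
#' ep <- simulate_epochs(d, participant_profile(),
#'                       condition = list(frequency_hz = 1000, snr_db = 15,
#'                                        repetition = 1), seed = 1)
#' dim(ep)
#' @export
simulate_epochs <- function(design, profile, condition,
                            channel_role = c("ipsi", "contra"), seed = 1L) {
  channel_role <- match.arg(channel_role)
  validate_design(design)
  condition <- as.list(condition)
  if (!condition$frequency_hz %in% design$frequencies_hz ||
      !condition$snr_db %in% design$snr_levels_db ||
      !condition$repetition %in% seq_len(design$repetitions)) {
    stop("condition (", condition$frequency_hz, " Hz, ", condition$snr_db,
         " dB, rep ", condition$repetition, ") is not in the design grid",
         call. = FALSE)
  }
  amp <- embedded_amplitude(profile, condition$frequency_hz, condition$snr_db,
                            condition$repetition, channel_role)
  n <- design$sweeps
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)

  data <- shaped_noise(n, design$n_samples, design$fs, profile$noise_rms_uv)
  if (amp > 0) {
    # split peak-to-peak 60/40 between N1 and P2, typical of adult responses
    jitter_s <- stats::rnorm(n, 0, profile$latency_jitter_ms / 1000)
    # keep jittered latencies inside the search windows
    jitter_s <- pmax(pmin(jitter_s, 0.018), -0.018)
    for (i in seq_len(n)) {
      data[i, ] <- data[i, ] + acc_template(
        design,
        n1_amp_uv = 0.6 * amp, p2_amp_uv = 0.4 * amp,
        n1_lat_s = 1.100 + jitter_s[i], p2_lat_s = 1.200 + jitter_s[i]
      )
    }
  }
  if (profile$artifact_rate > 0) {
    is_art <- stats::runif(n) < profile$artifact_rate
    n_art <- sum(is_art)
    if (n_art > 0) {
      data[is_art, ] <- shaped_noise(n_art, design$n_samples, design$fs,
                                     10 * profile$noise_rms_uv)
    }
  }
  acc_epochs(data, design, channel_role = channel_role, condition = condition,
             seed = as.integer(seed))
}
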