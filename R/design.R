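#' Stimulus design for an ACC recording session
#'
#' Builds the timing and condition grid that every stage of the pipeline
#' reads: sampling rate, event times within an epoch, the SNR ladder, tone
#' frequencies, sweep count, and the analysis windows for the N1 and P2
#' peaks and for the signal/noise-floor RMS segments.
#'
#' Times are in seconds relative to the onset of the ongoing masking noise
#' (TEN) at 0 s. With the defaults the tone starts at 1 s, lasts 0.5 s, and
#' each epoch spans -0.1 to 2.5 s at 2048 Hz. Epoch length in samples is
#' `round((epoch_end_s - epoch_start_s) * fs)` and all windows follow a
#' half-open sample convention `[start, end)`.
#'
#' @param ... named overrides of any design field (see Details).
#'
#' @details Fields and defaults:
#' \describe{
#'   \item{fs}{sampling rate, Hz (2048)}
#'   \item{ten_onset_s}{masker onset (0)}
#'   \item{tone_onset_s}{tone onset (1)}
#'   \item{tone_dur_s}{tone duration (0.5)}
#'   \item{stim_offset_s}{stimulus offset (1.5)}
#'   \item{epoch_start_s, epoch_end_s}{epoch limits (-0.1, 2.5)}
#'   \item{isi_s}{inter-stimulus interval (1.5)}
#'   \item{snr_levels_db}{tone-to-masker SNR ladder (15, 12, ..., 0)}
#'   \item{frequencies_hz}{tone frequencies (1000, 4000)}
#'   \item{sweeps}{epochs per condition (120)}
#'   \item{repetitions}{recordings per condition (2)}
#'   \item{n1_window_s}{N1 search window (1.080, 1.120)}
#'   \item{p2_window_s}{P2 search window (1.170, 1.230)}
#'   \item{rms_signal_window_s}{response RMS window (1.080, 1.230)}
#'   \item{rms_noise_window_s}{noise-floor RMS window (1.580, 1.730)}
#' }
#'
#' @return An object of class `acc_design` (a named list with the fields
#'   above plus `n_samples` and `time_s`, the per-sample time axis).
#' @examples
#' d <- acc_design()
#' d$n_samples
#' acc_design(fs = 256, sweeps = 30)
#' @export
acc_design <- function(...) {
  design <- list(
    fs = 2048,
    ten_onset_s = 0,
    tone_onset_s = 1,
    tone_dur_s = 0.5,
    stim_offset_s = 1.5,
    epoch_start_s = -0.1,
    epoch_end_s = 2.5,
    isi_s = 1.5,
    snr_levels_db = seq(15, 0, by = -3),
    frequencies_hz = c(1000, 4000),
    sweeps = 120,
    repetitions = 2,
    n1_window_s = c(1.080, 1.120),
    p2_window_s = c(1.170, 1.230),
    rms_signal_window_s = c(1.080, 1.230),
    rms_noise_window_s = c(1.580, 1.730)
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(design))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown design field(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    design[names(overrides)] <- overrides
  }
  design$n_samples <- round((design$epoch_end_s - design$epoch_start_s) * design$fs)
  design$time_s <- design$epoch_start_s + (seq_len(design$n_samples) - 1) / design$fs
  design <- structure(design, class = "acc_design")
  validate_design(design)
  design
}

# Invariant checks; returns the design invisibly so the constructor can
# tail-call it.
validate_design <- function(design) {
  stopifnot(inherits(design, "acc_design"))
  if (design$fs <= 0) stop("fs must be positive", call. = FALSE)
  if (design$epoch_end_s <= design$stim_offset_s + 0.23) {
    stop("epoch_end_s must exceed stim_offset_s + 0.23 s so the noise-floor ",
         "window fits inside the epoch", call. = FALSE)
  }
  windows <- list(
    n1_window_s = design$n1_window_s,
    p2_window_s = design$p2_window_s,
    rms_signal_window_s = design$rms_signal_window_s,
    rms_noise_window_s = design$rms_noise_window_s
  )
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (length(w) != 2 || w[1] >= w[2]) {
      stop(nm, " must be an increasing (start, end) pair", call. = FALSE)
    }
    if (w[1] < design$epoch_start_s || w[2] > design$epoch_end_s) {
      stop(nm, " lies outside the epoch [", design$epoch_start_s, ", ",
           design$epoch_end_s, "] s", call. = FALSE)
    }
  }
  steps <- diff(sort(design$snr_levels_db))
  if (length(steps) > 1 && any(abs(steps - steps[1]) > 1e-9)) {
    stop("snr_levels_db must be uniformly spaced", call. = FALSE)
  }
  invisible(design)
}

#' @export
print.acc_design <- function(x, ...) {
  cat("<acc_design>\n")
  cat(sprintf("  fs: %g Hz, epoch [%g, %g] s (%d samples)\n",
              x$fs, x$epoch_start_s, x$epoch_end_s, x$n_samples))
  cat(sprintf("  tone: %g s onset, %g s duration; masker offset %g s\n",
              x$tone_onset_s, x$tone_dur_s, x$stim_offset_s))
  cat(sprintf("  grid: SNR {%s} dB x {%s} Hz x %d repetitions, %d sweeps\n",
              paste(x$snr_levels_db, collapse = ","),
              paste(x$frequencies_hz, collapse = ","),
              x$repetitions, x$sweeps))
  invisible(x)
}

#' Design bookkeeping
#'
#' Derived quantities of an [acc_design()]: the number of recorded conditions
#' per participant, the planned number of recordings for a cohort, and the
#' total stimulus time per frequency.
#'
#' @param design an [acc_design()].
#' @param n_participants cohort size.
#' @return A one-row tibble with columns `n_conditions_per_participant`,
#'   `planned_recordings`, and `stimulus_minutes_per_frequency`.
#' @examples
#' design_summary(acc_design(), n_participants = 23)
#' @export
design_summary <- function(design = acc_design(), n_participants = 1) {
  validate_design(design)
  n_cond <- length(design$snr_levels_db) * length(design$frequencies_hz) *
    design$repetitions
  sweep_time_s <- (design$stim_offset_s - design$ten_onset_s) + design$isi_s
  per_freq_s <- sweep_time_s * design$sweeps * length(design$snr_levels_db)
  tibble::tibble(
    n_conditions_per_participant = n_cond,
    planned_recordings = n_participants * n_cond,
    stimulus_minutes_per_frequency = per_freq_s / 60
  )
}

# Half-open sample index range [start, end) for a window in seconds.
window_idx <- function(design, window_s) {
  idx <- which(design$time_s >= window_s[1] & design$time_s < window_s[2])
  if (!length(idx)) stop("window [", window_s[1], ", ", window_s[2],
                         ") contains no samples", call. = FALSE)
  idx
}
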