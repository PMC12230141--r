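new_detection <- function(method, statistic = NA_real_, criterion = NA_real_,
                          outcome, n_boot = NA_integer_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          seed = NA_integer_, note = NA_character_) {
  tibble::tibble(
    method = method, statistic = statistic, criterion = criterion,
    outcome = outcome, n_boot = n_boot,
    ci_lower = ci_lower, ci_upper = ci_upper,
    seed = seed, note = note
  )
}

#' RMS-ratio detection of an ACC response
#'
#' The response is declared present when the RMS of the averaged waveform
#' over the response window (80-230 ms after tone onset) is at least 50%
#' higher than the RMS over the noise-floor window (80-230 ms after stimulus
#' offset): statistic = signal RMS / noise RMS, present iff statistic >= 1.5
#' (boundary inclusive). An inconclusive average (all epochs rejected)
#' yields an inconclusive outcome, never a guess.
#'
#' By default the numerator is the RMS of the waveform segment; set
#' `peak_rms = TRUE` to use `|N1-P2| / sqrt(2)` instead (the alternative
#' reading of "RMS of N1-P2 amplitude" for a two-point quantity).
#'
#' @param avg an `acc_average` (see [average_epochs()]).
#' @param design an [acc_design()]; taken from `avg` when omitted.
#' @param criterion detection ratio (default 1.5).
#' @param peak_rms use the peak-to-peak-based numerator (default `FALSE`).
#' @return One-row detection tibble: `method`, `statistic`, `criterion`,
#'   `outcome` ("present", "absent" or "inconclusive"), and bookkeeping
#'   columns shared with the other detectors.
#' @export
detect_rms <- function(avg, design = NULL, criterion = 1.5, peak_rms = FALSE) {
  if (inherits(avg, "acc_average") && avg$inconclusive) {
    return(new_detection("rms", criterion = criterion, outcome = "inconclusive"))
  }
  if (inherits(avg, "acc_average")) design <- avg$design
  signal_rms <- if (peak_rms) {
    abs(find_peaks(avg, design)$n1p2_amp_uv) / sqrt(2)
  } else {
    segment_rms(avg, design$rms_signal_window_s, design)
  }
  noise_rms <- segment_rms(avg, design$rms_noise_window_s, design)
  note <- NA_character_
  if (noise_rms == 0) {
    stat <- Inf
    note <- "zero noise-floor RMS; statistic infinite"
    warning(note, call. = FALSE)
  } else {
    stat <- signal_rms / noise_rms
  }
  new_detection("rms", statistic = stat, criterion = criterion,
                outcome = if (stat >= criterion) "present" else "absent",
                note = note)
}

#' Repetition-SNR (BSA-style) detection of an ACC response
#'
#' Compares the two repetitions of a recording: with N1-P2 amplitudes a1, a2
#' from each repetition's average, the statistic is
#' `20*log10(mean(a1, a2) / sd(a1, a2))` (sample SD of the two values) and
#' the response is present when it exceeds 3 dB. Identical repetitions give
#' SD = 0, an infinite statistic, and a present outcome (logged). With
#' `scale = "linear"` the ratio itself is compared against the criterion
#' instead (present iff mean/SD >= criterion, default 3).
#'
#' @param avg_rep1,avg_rep2 `acc_average` objects for the two repetitions.
#' @param design an [acc_design()]; taken from the averages when omitted.
#' @param criterion_db dB criterion (default 3).
#' @param scale `"db"` (default) or `"linear"`.
#' @return One-row detection tibble (see [detect_rms()]).
#' @examples
#' # a1 = 10, a2 = 4: mean 7, sd 4.243 -> 4.35 dB -> present
#' @export
detect_bsa <- function(avg_rep1, avg_rep2, design = NULL, criterion_db = 3,
                       scale = c("db", "linear")) {
  scale <- match.arg(scale)
  inconc <- function(a) inherits(a, "acc_average") && a$inconclusive
  if (inconc(avg_rep1) || inconc(avg_rep2)) {
    return(new_detection("bsa", criterion = criterion_db, outcome = "inconclusive"))
  }
  if (is.null(design)) design <- avg_rep1$design
  a1 <- find_peaks(avg_rep1, design)$n1p2_amp_uv
  a2 <- find_peaks(avg_rep2, design)$n1p2_amp_uv
  m <- mean(c(a1, a2))
  s <- stats::sd(c(a1, a2))
  note <- NA_character_
  if (s == 0) {
    stat <- Inf
    note <- "identical repetition amplitudes; statistic infinite"
    present <- TRUE
  } else if (m <= 0) {
    # non-positive mean peak-to-peak amplitude: no response by construction
    stat <- if (scale == "db") -Inf else m / s
    present <- FALSE
  } else if (scale == "db") {
    stat <- 20 * log10(m / s)
    present <- stat > criterion_db
  } else {
    stat <- m / s
    present <- stat >= criterion_db
  }
  new_detection("bsa", statistic = stat, criterion = criterion_db,
                outcome = if (present) "present" else "absent", note = note)
}

# Fast polarity-flip bootstrap average: equivalent to drawing `m` epochs
# with replacement from the pool and flipping each draw's sign
# independently. Draw counts are multinomial over epochs; the signed count
# for an epoch drawn k times is 2*Binomial(k, 1/2) - k. The resampled
# average is then a single weighted combination of pool rows.
boot_signed_average <- function(pool, m) {
  n <- nrow(pool)
  counts <- stats::rmultinom(1, m, rep(1 / n, n))[, 1]
  signed <- 2 * stats::rbinom(n, counts, 0.5) - counts
  as.numeric(crossprod(pool, signed)) / m
}

#' Bootstrap detection of an ACC response
#'
#' Pools the accepted ipsilateral and contralateral epochs of a condition
#' into a single set, computes the observed statistic (N1-P2 amplitude of
#' the pooled average divided by the noise-floor RMS of that average), and
#' builds a null distribution by `n_boot` resamples: each resample draws
#' `resample_size` epochs with replacement from the pool, flips each drawn
#' epoch's polarity independently at random (destroying the phase-locked
#' response while preserving the noise spectrum), averages, and recomputes
#' the statistic. The response is present when the observed statistic
#' exceeds the upper bound of the null's central `1 - alpha` interval
#' (one-sided decision: only a response larger than noise is meaningful).
#'
#' With `null = "resample"` the plain with-replacement bootstrap (no
#' polarity flips) is used instead and the interval describes the sampling
#' uncertainty of the observed statistic; the response is then present when
#' the interval's lower bound exceeds 1.
#'
#' @param epochs_ipsi,epochs_contra [acc_epochs()] objects for the two
#'   channels (pass `NULL` for a single-channel decision).
#' @param design an [acc_design()]; taken from the epochs when omitted.
#' @param n_boot bootstrap iterations (default 499; fewer than 99 draws a
#'   warning).
#' @param resample_size epochs per resample; defaults to the pooled number
#'   of accepted epochs, so that the null resamples match the observed
#'   average's sample size (240 for the full design with both channels
#'   pooled). Drawing more epochs than the pool holds narrows the null and
#'   inflates the false-present rate.
#' @param alpha two-sided interval level (default 0.05).
#' @param seed integer seed (required for reproducible pipelines).
#' @param null `"flip"` (default) or `"resample"`, see Details.
#' @return One-row detection tibble with `statistic` (observed), `ci_lower`
#'   and `ci_upper` (null interval), `n_boot`, and the outcome.
#' @export
detect_bootstrap <- function(epochs_ipsi, epochs_contra = NULL, design = NULL,
                             n_boot = 499, resample_size = NULL, alpha = 0.05,
                             seed = 1L, null = c("flip", "resample")) {
  null <- match.arg(null)
  if (n_boot < 99) warning("n_boot < 99 gives unstable interval estimates", call. = FALSE)
  sets <- Filter(Negate(is.null), list(epochs_ipsi, epochs_contra))
  stopifnot(length(sets) >= 1, all(vapply(sets, inherits, TRUE, "acc_epochs")))
  if (is.null(design)) design <- sets[[1]]$design
  pool <- do.call(rbind, lapply(sets, function(e) e$data[e$accepted, , drop = FALSE]))
  if (is.null(pool) || nrow(pool) < 2) {
    return(new_detection("bootstrap", outcome = "inconclusive",
                         n_boot = as.integer(n_boot), seed = as.integer(seed)))
  }
  n1_idx <- window_idx(design, design$n1_window_s)
  p2_idx <- window_idx(design, design$p2_window_s)
  nf_idx <- window_idx(design, design$rms_noise_window_s)
  stat_of <- function(w) {
    p2p <- max(w[p2_idx]) - min(w[n1_idx])
    nf <- sqrt(mean(w[nf_idx]^2))
    if (nf == 0) Inf else p2p / nf
  }
  if (is.null(resample_size) || is.na(resample_size)) resample_size <- nrow(pool)
  observed <- stat_of(colMeans(pool))

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  null_stats <- numeric(n_boot)
  n <- nrow(pool)
  for (b in seq_len(n_boot)) {
    if (null == "flip") {
      null_stats[b] <- stat_of(boot_signed_average(pool, resample_size))
    } else {
      idx <- sample.int(n, resample_size, replace = TRUE)
      counts <- tabulate(idx, nbins = n)
      null_stats[b] <- stat_of(as.numeric(crossprod(pool, counts)) / resample_size)
    }
  }
  ci <- stats::quantile(null_stats, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                        type = 7)
  present <- if (null == "flip") observed > ci[2] else ci[1] > 1
  out <- new_detection("bootstrap", statistic = observed, criterion = ci[2],
                       outcome = if (present) "present" else "absent",
                       n_boot = as.integer(n_boot), ci_lower = ci[1],
                       ci_upper = ci[2], seed = as.integer(seed))
  out$resample_size <- as.integer(resample_size)
  out
}
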