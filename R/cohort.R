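#' Simulate a whole cohort
#'
#' Generates every (participant, frequency, SNR, repetition, channel) cell
#' of the design grid as an [acc_epochs()] object, together with each
#' participant's profile and a simulated behavioural staircase threshold
#' (signal-to-TEN ratio). Per-cell seeds are derived deterministically from
#' `seed`, so a cohort is bit-reproducible. Attrition, when requested,
#' removes a random fraction of recordings (both channels of the affected
#' recording); it is never applied silently.
#'
#' @param design an [acc_design()].
#' @param n_participants cohort size (>= 1).
#' @param dr_spec `NULL` for none, or a named numeric vector mapping
#'   participant ids (e.g. `"p02"`) to the SNR below which their ACC is
#'   suppressed (simulated dead region).
#' @param profiles optional list of [participant_profile()]s, one per
#'   participant; defaults are drawn with mild between-subject variation.
#' @param attrition_fraction fraction of (participant, frequency, snr,
#'   repetition) recordings to drop at random (default 0, opt-in).
#' @param seed master integer seed.
#' @return A list with `manifest` (a tibble: participant, frequency_hz,
#'   snr_db, repetition, channel, seed, present), `epochs` (named list of
#'   [acc_epochs()], names matching `manifest$key`), `profiles`, and
#'   `behavioural` (a tibble of staircase thresholds per participant and
#'   frequency).
#' @examples
#' co <- simulate_cohort(acc_design(fs = 128, sweeps = 6), 1, seed = 1)
#' nrow(co$manifest)  # 48 = 2 freq x 6 SNR x 2 rep x 2 channels
#' @export
simulate_cohort <- function(design, n_participants, dr_spec = NULL,
                            profiles = NULL, attrition_fraction = 0,
                            seed = 1L) {
  validate_design(design)
  stopifnot(n_participants >= 1)
  ids <- sprintf("p%02d", seq_len(n_participants))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)

  if (is.null(profiles)) {
    profiles <- lapply(ids, function(id) {
      participant_profile(
        id = id,
        acc_amp_at_max_snr_uv = c("1000" = stats::rnorm(1, 8, 1),
                                  "4000" = stats::rnorm(1, 6, 0.8)),
        noise_rms_uv = stats::rnorm(1, 10, 1.5),
        behavioural_str_db = stats::runif(1, -6, 2),
        dr_suppression_snr_db = if (!is.null(dr_spec) && id %in% names(dr_spec))
          dr_spec[[id]] else NA_real_
      )
    })
    names(profiles) <- ids
  } else {
    stopifnot(length(profiles) == n_participants)
    names(profiles) <- ids
  }

  grid <- tidyr::expand_grid(
    participant = ids,
    frequency_hz = design$frequencies_hz,
    snr_db = design$snr_levels_db,
    repetition = seq_len(design$repetitions),
    channel = c("ipsi", "contra")
  )
  grid$key <- with(grid, paste(participant, frequency_hz, snr_db,
                               repetition, channel, sep = "_"))
  grid$seed <- split_seed(seed, grid$key)

  # attrition acts on recordings (both channels together)
  rec <- unique(grid[, c("participant", "frequency_hz", "snr_db", "repetition")])
  n_drop <- round(attrition_fraction * nrow(rec))
  dropped_rec <- if (n_drop > 0) sample(nrow(rec), n_drop) else integer(0)
  rec$present <- !(seq_len(nrow(rec)) %in% dropped_rec)
  grid <- dplyr::left_join(grid, rec,
                           by = c("participant", "frequency_hz", "snr_db",
                                  "repetition"))

  epochs <- list()
  for (i in seq_len(nrow(grid))) {
    if (!grid$present[i]) next
    epochs[[grid$key[i]]] <- simulate_epochs(
      design, profiles[[grid$participant[i]]],
      condition = list(frequency_hz = grid$frequency_hz[i],
                       snr_db = grid$snr_db[i],
                       repetition = grid$repetition[i]),
      channel_role = grid$channel[i],
      seed = grid$seed[i]
    )
  }

  behavioural <- tidyr::expand_grid(participant = ids,
                                    frequency_hz = design$frequencies_hz)
  behavioural <- dplyr::rowwise(behavioural)
  behavioural <- dplyr::mutate(behavioural, str_db = {
    pr <- profiles[[participant]]
    sc <- simulate_staircase(pr$behavioural_str_db, start_db = 10,
                             seed = split_seed(seed, paste0("stair_", participant,
                                                            "_", frequency_hz)))
    sc$threshold_db
  })
  behavioural <- dplyr::ungroup(behavioural)

  list(manifest = tibble::as_tibble(grid), epochs = epochs,
       profiles = profiles, behavioural = behavioural)
}

# Deterministic per-key seed derived from the master seed: a small rolling
# hash of the key string folded with the master seed, kept below 2^31.
split_seed <- function(master, keys) {
  vapply(keys, function(k) {
    h <- as.double(master %% 2147483647)
    for (ch in utf8ToInt(k)) h <- (h * 31 + ch) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}
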