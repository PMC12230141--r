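#' Simulate an adaptive staircase
#'
#' Transformed up-down staircase with asymmetric steps, as used for masked
#' and absolute threshold measurement: under the `"2-down-1-up"` rule the
#' level drops by `down_step_db` after two consecutive correct responses and
#' rises by `up_step_db` after any incorrect response; `"1-down-1-up"` drops
#' after every correct response. The simulated listener answers correctly
#' with probability `plogis(psychometric_slope * (level - true_threshold))`,
#' so a large slope approximates a deterministic step-function listener.
#'
#' The run stops after `n_reversals_stop` reversals or `max_trials` trials,
#' whichever comes first; stopping on the trial cap (or pinning at
#' `floor_db`) flags the estimate. The threshold estimate is the mean of the
#' last `n_estimate_reversals` reversal levels.
#'
#' @param true_threshold_db listener's true threshold, dB.
#' @param start_db starting level, dB (default 70, the clinical start).
#' @param down_step_db,up_step_db step sizes, dB (defaults 4 and 2).
#' @param psychometric_slope logistic slope, 1/dB (default 5, near-step).
#' @param rule `"2-down-1-up"` (default) or `"1-down-1-up"`.
#' @param n_reversals_stop reversals before stopping (default 8).
#' @param n_estimate_reversals reversals averaged for the estimate
#'   (default 4).
#' @param max_trials trial cap (default 60).
#' @param floor_db lowest presentable level (default -20).
#' @param seed integer seed.
#' @return A list with `threshold_db` (mean of the final reversals),
#'   `flagged` (`TRUE` when the run hit the trial cap or the floor),
#'   `reversals` (levels at reversals), and `track` (a tibble of
#'   trial, level, correct).
#' @examples
#' simulate_staircase(0, start_db = 15, seed = 1)$threshold_db
#' @export
simulate_staircase <- function(true_threshold_db, start_db = 70,
                               down_step_db = 4, up_step_db = 2,
                               psychometric_slope = 5,
                               rule = c("2-down-1-up", "1-down-1-up"),
                               n_reversals_stop = 8,
                               n_estimate_reversals = 4,
                               max_trials = 60, floor_db = -20, seed = 1L) {
  rule <- match.arg(rule)
  stopifnot(down_step_db > 0, up_step_db > 0, psychometric_slope > 0)
  need_correct <- if (rule == "2-down-1-up") 2L else 1L
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)

  level <- start_db
  cc <- 0L                 # consecutive correct count
  last_dir <- 0L           # -1 down, +1 up
  reversals <- numeric(0)
  trial <- 0L
  levels <- correct <- vector("numeric", 0)
  hit_floor <- FALSE
  while (trial < max_trials && length(reversals) < n_reversals_stop) {
    trial <- trial + 1L
    p <- stats::plogis(psychometric_slope * (level - true_threshold_db))
    ans <- stats::runif(1) < p
    levels[trial] <- level
    correct[trial] <- ans
    if (ans) {
      cc <- cc + 1L
      if (cc >= need_correct) {
        if (last_dir == 1L) reversals <- c(reversals, level)
        last_dir <- -1L
        level <- level - down_step_db
        cc <- 0L
      }
    } else {
      if (last_dir == -1L) reversals <- c(reversals, level)
      last_dir <- 1L
      level <- level + up_step_db
      cc <- 0L
    }
    if (level < floor_db) {
      level <- floor_db
      hit_floor <- TRUE
    }
  }
  flagged <- hit_floor || length(reversals) < n_reversals_stop
  est <- if (length(reversals)) {
    k <- min(n_estimate_reversals, length(reversals))
    mean(utils::tail(reversals, k))
  } else {
    level  # never reversed: report the last level, flagged above
  }
  list(
    threshold_db = est,
    flagged = flagged,
    reversals = reversals,
    track = tibble::tibble(trial = seq_len(trial),
                           level = levels, correct = as.logical(correct))
  )
}
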