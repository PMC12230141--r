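#' Estimate the ACC threshold from per-SNR detection outcomes
#'
#' The ACC threshold is the lowest SNR level L at which the response is
#' present, with the response also present at L+3 dB (when L+3 is on the
#' grid) and absent at L-3 dB (when L-3 is on the grid). Clauses that fall
#' off the grid are vacuous, so the grid minimum can qualify without an
#' "absent below" check and the grid maximum without a "present above"
#' check. Inconclusive cells are treated as missing: any clause that would
#' read them is vacuous, and the result is flagged. The rule is applied
#' literally to non-monotone patterns; the lowest qualifying L wins.
#'
#' @param outcomes data frame with columns `snr_db` and `outcome`
#'   ("present" / "absent" / "inconclusive"); missing grid levels are
#'   allowed and treated as inconclusive.
#' @param design an [acc_design()] supplying the SNR grid.
#' @return A one-row tibble: `threshold_db_snr` (`NA` when undetermined),
#'   `determined`, `pattern` (one letter per grid level, low to high:
#'   P/A/I/M), `any_inconclusive`, and `reason`.
#' @examples
#' d <- acc_design()
#' out <- tibble::tibble(snr_db = c(0, 3, 6, 9, 12, 15),
#'                       outcome = c("absent", "absent", "present",
#'                                   "present", "present", "present"))
#' estimate_threshold(out, d)  # threshold 6
#' @export
estimate_threshold <- function(outcomes, design) {
  validate_design(design)
  outcomes <- as.data.frame(outcomes)
  if (!nrow(outcomes)) stop("empty outcome list", call. = FALSE)
  stopifnot(all(c("snr_db", "outcome") %in% names(outcomes)))
  grid <- sort(design$snr_levels_db)
  step <- if (length(grid) > 1) grid[2] - grid[1] else 3
  state <- vapply(grid, function(l) {
    row <- outcomes[outcomes$snr_db == l, , drop = FALSE]
    if (!nrow(row)) "missing" else row$outcome[1]
  }, character(1))

  present_at <- function(l) {
    if (!l %in% grid) return(TRUE)        # off-grid: clause vacuous
    s <- state[match(l, grid)]
    if (s %in% c("inconclusive", "missing")) return(TRUE)
    s == "present"
  }
  absent_at <- function(l) {
    if (!l %in% grid) return(TRUE)
    s <- state[match(l, grid)]
    if (s %in% c("inconclusive", "missing")) return(TRUE)
    s == "absent"
  }
  qualifies <- function(l) {
    s <- state[match(l, grid)]
    s == "present" && present_at(l + step) && absent_at(l - step)
  }
  hit <- grid[vapply(grid, qualifies, logical(1))]
  threshold <- if (length(hit)) min(hit) else NA_real_
  pattern <- paste(vapply(state, function(s) switch(
    s, present = "P", absent = "A", inconclusive = "I", missing = "M"),
    character(1)), collapse = "")
  tibble::tibble(
    threshold_db_snr = threshold,
    determined = !is.na(threshold),
    pattern = pattern,
    any_inconclusive = any(state %in% c("inconclusive", "missing")),
    reason = if (!is.na(threshold)) {
      sprintf("lowest L=%g with present at L, L+%g and absent at L-%g (off-grid/inconclusive clauses vacuous)",
              threshold, step, step)
    } else "no level satisfies the present/present-above/absent-below rule"
  )
}

#' Dead-region screening rules
#'
#' Applies two independent screens for a cochlear dead region at one test
#' frequency: the electrophysiological rule (ACC threshold at or above a
#' cutoff, default 12 dB SNR) and the behavioural TEN rule (masked threshold
#' at least 10 dB above the TEN level AND at least 10 dB above the absolute
#' threshold; both criteria must hold).
#'
#' @param acc_threshold_db_snr ACC threshold in dB SNR, or `NA` when
#'   undetermined.
#' @param masked_threshold_dbhl,ten_level_dbhl,absolute_threshold_dbhl
#'   behavioural levels in dB HL (any may be `NA`, making the behavioural
#'   rule `NA`).
#' @param acc_cutoff_db electrophysiological cutoff (default 12 dB SNR).
#' @return A one-row tibble: `acc_rule_positive` (`NA` when the ACC
#'   threshold is undetermined), `ten_rule_positive`, and the echoed inputs.
#' @examples
#' classify_dead_region(12, 75, 60, 20)
#' @export
classify_dead_region <- function(acc_threshold_db_snr,
                                 masked_threshold_dbhl = NA_real_,
                                 ten_level_dbhl = NA_real_,
                                 absolute_threshold_dbhl = NA_real_,
                                 acc_cutoff_db = 12) {
  acc_rule <- if (is.na(acc_threshold_db_snr)) NA else
    acc_threshold_db_snr >= acc_cutoff_db
  ten_rule <- if (any(is.na(c(masked_threshold_dbhl, ten_level_dbhl,
                              absolute_threshold_dbhl)))) NA else
    (masked_threshold_dbhl >= ten_level_dbhl + 10) &&
    (masked_threshold_dbhl >= absolute_threshold_dbhl + 10)
  tibble::tibble(
    acc_rule_positive = acc_rule,
    ten_rule_positive = ten_rule,
    acc_threshold_db_snr = acc_threshold_db_snr,
    masked_threshold_dbhl = masked_threshold_dbhl,
    ten_level_dbhl = ten_level_dbhl,
    absolute_threshold_dbhl = absolute_threshold_dbhl,
    acc_cutoff_db = acc_cutoff_db
  )
}
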