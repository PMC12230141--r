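#' Published Bland-Altman reference tables
#'
#' Bias and 95% limits of agreement (with CIs) from a published ACC
#' threshold method-comparison and repeatability study, shipped as package
#' data. They serve as inputs for internal-consistency checks of the
#' Bland-Altman arithmetic: the midpoint of the limits must reproduce the
#' bias, and the coefficient of repeatability can be back-derived from the
#' limits alone.
#'
#' @return A tibble with columns `table` ("agreement" or "repeatability"),
#'   `comparison`, `frequency_khz`, `term` ("bias", "loa_lower",
#'   "loa_upper"), `value`, `ci_lower`, `ci_upper`; values in dB SNR.
#' @export
reference_loa_tables <- function() {
  path <- system.file("extdata", "reference_loa_tables.csv",
                      package = "accdetect", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path))
}

#' Back-derive repeatability coefficients from printed limits of agreement
#'
#' Given a row pair of published 95% limits of agreement, the SD of the
#' test-retest differences is `(upper - lower) / (2 * 1.96)` and the
#' coefficient of repeatability is twice that SD. Applied to the shipped
#' repeatability reference table (see [reference_loa_tables()]).
#'
#' @return A tibble: `comparison` (method), `frequency_khz`, `loa_lower`,
#'   `loa_upper`, `sd_diff`, `cor` (dB SNR).
#' @examples
#' derive_repeatability_coefficients()
#' @export
derive_repeatability_coefficients <- function() {
  ref <- reference_loa_tables()
  rep_tab <- ref[ref$table == "repeatability", ]
  wide <- tidyr::pivot_wider(rep_tab[, c("comparison", "frequency_khz",
                                         "term", "value")],
                             names_from = "term", values_from = "value")
  z <- 1.96  # the conventional multiplier the printed limits use
  dplyr::mutate(wide,
                sd_diff = (.data$loa_upper - .data$loa_lower) / (2 * z),
                cor = 2 * .data$sd_diff)[, c("comparison", "frequency_khz",
                                             "loa_lower", "loa_upper",
                                             "sd_diff", "cor")]
}

#' Check printed Bland-Altman rows for bias/limits symmetry
#'
#' For every row of the shipped agreement reference table, computes the
#' midpoint of the printed limits of agreement; by construction of the
#' Bland-Altman limits this must equal the printed bias.
#'
#' @return A tibble: `comparison`, `frequency_khz`, `bias`, `loa_midpoint`,
#'   `deviation` (midpoint minus bias, dB SNR).
#' @export
check_loa_consistency <- function() {
  ref <- reference_loa_tables()
  agr <- ref[ref$table == "agreement", ]
  wide <- tidyr::pivot_wider(agr[, c("comparison", "frequency_khz", "term",
                                     "value")],
                             names_from = "term", values_from = "value")
  dplyr::mutate(wide,
                loa_midpoint = (.data$loa_lower + .data$loa_upper) / 2,
                deviation = .data$loa_midpoint - .data$bias)[
    , c("comparison", "frequency_khz", "bias", "loa_midpoint", "deviation")]
}
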