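#' Bland-Altman limits of agreement
#'
#' Classical Bland-Altman comparison of two paired measurement series:
#' bias = mean difference, 95% limits of agreement = bias +/- 1.96 * SD of
#' the differences, with 95% confidence intervals (t-based for the bias;
#' `LoA +/- t * sqrt(3 * SD^2 / n)` for each limit).
#'
#' With `repeated = TRUE` and a `subject` grouping vector, the variance of
#' the differences is corrected for replicate pairs per subject under the
#' assumption of a constant true value: a one-way ANOVA of the differences
#' on subject gives the within-subject mean square and a between-subject
#' variance component, and the corrected SD is the square root of their sum.
#' `repeated = TRUE` without a subject key falls back to the plain SD (a
#' note is recorded in the result).
#'
#' @param x,y paired numeric vectors; pairs with a missing member are
#'   dropped. At least 3 complete pairs are required.
#' @param repeated apply the replicate-pairs variance correction.
#' @param subject optional grouping vector (same length as `x`) identifying
#'   the subject each pair belongs to.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return An object of class `acc_agreement`: list with `n`, `bias`,
#'   `sd_diff`, `loa_lower`, `loa_upper`, `ci_bias`, `ci_loa_lower`,
#'   `ci_loa_upper`, `repeated`, `note`, and the differences. Use
#'   [generics::tidy()] / [generics::glance()] for tabular forms.
#' @examples
#' ba <- bland_altman(c(1, 2, 3, 4, 6), c(2, 2, 4, 5, 5))
#' tidy(ba)
#' @export
bland_altman <- function(x, y, repeated = FALSE, subject = NULL,
                         conf_level = 0.95) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  if (!is.null(subject)) {
    stopifnot(length(subject) == length(x))
    subject <- subject[keep]
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  sd_plain <- stats::sd(d)
  note <- NA_character_

  if (repeated && !is.null(subject) && length(unique(subject)) > 1 &&
      length(unique(subject)) < n) {
    # Replicate-pairs correction, constant true value: one-way ANOVA of the
    # differences on subject, then sd^2 = within MS + between component.
    g <- factor(subject)
    fit <- stats::aov(d ~ g)
    ms <- summary(fit)[[1]][["Mean Sq"]]
    msb <- ms[1]; msw <- ms[2]
    m_i <- tabulate(g)
    k <- length(m_i)
    m0 <- (sum(m_i)^2 - sum(m_i^2)) / ((k - 1) * sum(m_i))
    var_b <- max((msb - msw) / m0, 0)
    sd_diff <- sqrt(msw + var_b)
  } else {
    if (repeated) note <- "repeated=TRUE without usable subject grouping; plain SD used"
    sd_diff <- sd_plain
  }

  z <- 1.96  # the conventional Bland-Altman multiplier
  loa_lower <- bias - z * sd_diff
  loa_upper <- bias + z * sd_diff
  if (sd_diff == 0) warning("zero variance of differences; limits collapse to the bias",
                            call. = FALSE)
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sqrt(3 * sd_diff^2 / n)
  structure(list(
    n = n, bias = bias, sd_diff = sd_diff,
    loa_lower = loa_lower, loa_upper = loa_upper,
    ci_bias = bias + c(-1, 1) * tcrit * se_bias,
    ci_loa_lower = loa_lower + c(-1, 1) * tcrit * se_loa,
    ci_loa_upper = loa_upper + c(-1, 1) * tcrit * se_loa,
    conf_level = conf_level, repeated = repeated, note = note,
    differences = d, means = (x + y) / 2
  ), class = "acc_agreement")
}

#' @export
print.acc_agreement <- function(x, ...) {
  cat(sprintf("<acc_agreement> n = %d\n", x$n))
  cat(sprintf("  bias %.3f [%.3f, %.3f]\n", x$bias, x$ci_bias[1], x$ci_bias[2]))
  cat(sprintf("  LoA  [%.3f, %.3f] (SD of differences %.3f)\n",
              x$loa_lower, x$loa_upper, x$sd_diff))
  if (!is.null(x$cor)) cat(sprintf("  coefficient of repeatability %.3f\n", x$cor))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy acc_agreement
#' @export
tidy.acc_agreement <- function(x, ...) {
  out <- tibble::tibble(
    term = c("bias", "loa_lower", "loa_upper"),
    estimate = c(x$bias, x$loa_lower, x$loa_upper),
    conf_low = c(x$ci_bias[1], x$ci_loa_lower[1], x$ci_loa_upper[1]),
    conf_high = c(x$ci_bias[2], x$ci_loa_lower[2], x$ci_loa_upper[2])
  )
  if (!is.null(x$cor)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "cor", estimate = x$cor, conf_low = NA_real_, conf_high = NA_real_))
  }
  out
}

#' @method glance acc_agreement
#' @export
glance.acc_agreement <- function(x, ...) {
  tibble::tibble(n = x$n, bias = x$bias, sd_diff = x$sd_diff,
                 loa_lower = x$loa_lower, loa_upper = x$loa_upper,
                 cor = if (is.null(x$cor)) NA_real_ else x$cor,
                 repeated = x$repeated)
}

#' Test-retest repeatability of a measurement method
#'
#' Bland-Altman analysis of two repetitions of the same method with the
#' repeated-measures variance correction, plus the coefficient of
#' repeatability `cor = 2 * SD of the differences` — the value below which
#' 95% of repeat differences are expected to fall.
#'
#' @param rep1,rep2 paired numeric vectors (the two repetitions).
#' @param subject optional subject grouping, as in [bland_altman()].
#' @return An `acc_agreement` object with an additional `cor` element.
#' @examples
#' r <- repeatability(c(1, 2, 3, 5), c(2, 1, 4, 4))
#' r$cor
#' @export
repeatability <- function(rep1, rep2, subject = NULL) {
  ba <- bland_altman(rep1, rep2, repeated = TRUE, subject = subject)
  ba$cor <- 2 * ba$sd_diff
  ba
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `ccc = 2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' n-denominator sample moments. The confidence interval uses the Fisher
#' z-transform with Lin's asymptotic standard error; `ci = "bootstrap"`
#' gives a percentile bootstrap interval instead.
#'
#' @param x,y paired numeric vectors, at least 3 complete pairs, each with
#'   nonzero variance.
#' @param conf_level confidence level (default 0.95).
#' @param ci `"z"` (default, Fisher-z) or `"bootstrap"`.
#' @param n_boot bootstrap resamples when `ci = "bootstrap"`.
#' @param seed seed for the bootstrap interval.
#' @return A one-row tibble: `ccc`, `conf_low`, `conf_high`, `n`.
#' @examples
#' ccc(c(1, 2, 3, 4), c(2, 3, 4, 5))  # 0.714
#' @export
ccc <- function(x, y, conf_level = 0.95, ci = c("z", "bootstrap"),
                n_boot = 2000, seed = 1L) {
  ci <- match.arg(ci)
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  est <- function(x, y) {
    n <- length(x)
    sx2 <- stats::var(x) * (n - 1) / n
    sy2 <- stats::var(y) * (n - 1) / n
    sxy <- stats::cov(x, y) * (n - 1) / n
    2 * sxy / (sx2 + sy2 + (mean(x) - mean(y))^2)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  rho_c <- est(x, y)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (abs(rho_c) >= 1 - 1e-12) {
    # perfect (anti-)concordance: the z-transform degenerates
    lo <- hi <- rho_c
  } else if (ci == "z") {
    r <- stats::cor(x, y)
    # location-shift term of Lin's asymptotic variance
    sx <- stats::sd(x) * sqrt((n - 1) / n)
    sy <- stats::sd(y) * sqrt((n - 1) / n)
    u <- (mean(x) - mean(y)) / sqrt(sx * sy)
    z <- atanh(rho_c)
    se_z <- sqrt(((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
                    2 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
                    rho_c^4 * u^4 / (2 * r^2 * (1 - rho_c^2)^2)) / (n - 2))
    lo <- tanh(z - zcrit * se_z)
    hi <- tanh(z + zcrit * se_z)
  } else {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    boots <- replicate(n_boot, {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[i]) == 0 || stats::var(y[i]) == 0) NA_real_ else est(x[i], y[i])
    })
    qs <- stats::quantile(boots, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                          na.rm = TRUE, names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  tibble::tibble(ccc = rho_c, conf_low = lo, conf_high = hi, n = n)
}
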