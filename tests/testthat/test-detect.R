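make_average <- function(waveform, design) {
  structure(list(waveform = waveform, n_accepted = 10, n_rejected = 0,
                 inconclusive = FALSE, design = design,
                 channel_role = "ipsi",
                 condition = list(frequency_hz = 1000, snr_db = 15,
                                  repetition = 1)),
            class = "acc_average")
}

inconclusive_average <- function(design) {
  structure(list(waveform = NULL, n_accepted = 0, n_rejected = 10,
                 inconclusive = TRUE, design = design,
                 channel_role = "ipsi",
                 condition = list(frequency_hz = 1000, snr_db = 15,
                                  repetition = 1)),
            class = "acc_average")
}

# waveform with a controllable signal-window/noise-window RMS ratio
ratio_waveform <- function(design, ratio) {
  w <- numeric(design$n_samples)
  sig <- accdetect:::window_idx(design, design$rms_signal_window_s)
  noi <- accdetect:::window_idx(design, design$rms_noise_window_s)
  w[sig] <- ratio
  w[noi] <- 1
  w
}

test_that("RMS detection applies the inclusive 1.5 criterion to the ratio", {
  d <- small_design()
  r_hit <- detect_rms(make_average(ratio_waveform(d, 1.5), d))
  expect_equal(r_hit$statistic, 1.5)
  expect_equal(r_hit$outcome, "present")  # boundary inclusive

  r_miss <- detect_rms(make_average(ratio_waveform(d, 1.49), d))
  expect_equal(r_miss$outcome, "absent")

  # zero noise floor: infinite statistic, present, warned
  w <- ratio_waveform(d, 1); noi <- accdetect:::window_idx(d, d$rms_noise_window_s)
  w[noi] <- 0
  expect_warning(r_inf <- detect_rms(make_average(w, d)), "zero noise-floor")
  expect_equal(r_inf$statistic, Inf)
  expect_equal(r_inf$outcome, "present")

  expect_equal(detect_rms(inconclusive_average(d))$outcome, "inconclusive")
})

test_that("repetition-SNR detection reproduces hand-computed statistics", {
  d <- small_design()
  avg_amp <- function(a) make_average(acc_template(d, 0.6 * a, 0.4 * a), d)
  tmpl_p2p <- function(a) {
    w <- acc_template(d, 0.6 * a, 0.4 * a); max(w) - min(w)
  }

  # a1 = 10, a2 = 2: 20*log10(6 / 5.657) = 0.512 dB -> absent
  r1 <- detect_bsa(avg_amp(10), avg_amp(2))
  a1 <- tmpl_p2p(10); a2 <- tmpl_p2p(2)
  expect_equal(r1$statistic, 20 * log10(mean(c(a1, a2)) / sd(c(a1, a2))),
               tolerance = 1e-9)
  expect_equal(r1$statistic, 0.512, tolerance = 0.01)
  expect_equal(r1$outcome, "absent")

  # a1 = 10, a2 = 4: 4.35 dB -> present
  r2 <- detect_bsa(avg_amp(10), avg_amp(4))
  expect_equal(r2$statistic, 4.35, tolerance = 0.01)
  expect_equal(r2$outcome, "present")

  # identical repetitions: SD 0 -> infinite statistic, present
  r3 <- detect_bsa(avg_amp(5), avg_amp(5))
  expect_equal(r3$statistic, Inf)
  expect_equal(r3$outcome, "present")

  # linear-ratio reading of the criterion
  r4 <- detect_bsa(avg_amp(10), avg_amp(4), scale = "linear")
  expect_equal(r4$statistic, mean(c(a1, tmpl_p2p(4))) / sd(c(a1, tmpl_p2p(4))),
               tolerance = 1e-9)

  expect_equal(detect_bsa(inconclusive_average(d), avg_amp(5))$outcome,
               "inconclusive")
})

test_that("bootstrap detection is reproducible and detects a large response", {
  d <- small_design(sweeps = 30)
  pr <- quiet_profile(noise_rms_uv = 2)  # response ~6 uV vs 2 uV epochs
  ep <- simulate_epochs(d, pr, cond1(), seed = 11)
  b1 <- detect_bootstrap(ep, design = d, n_boot = 199, seed = 5)
  b2 <- detect_bootstrap(ep, design = d, n_boot = 199, seed = 5)
  expect_identical(b1, b2)
  expect_equal(b1$outcome, "present")
  expect_lte(b1$ci_lower, b1$ci_upper)
  # amplitude >> noise/sqrt(n): present for every seed
  for (s in 1:5) {
    expect_equal(detect_bootstrap(ep, design = d, n_boot = 199,
                                  seed = s)$outcome, "present")
  }

  # defaults: 499 iterations, resample size = pool size (240 for the full
  # two-channel design)
  expect_equal(formals(detect_bootstrap)$n_boot, 499)
  ep_a <- simulate_epochs(small_design(sweeps = 120), quiet_profile(), cond1(),
                          seed = 1)
  ep_b <- simulate_epochs(small_design(sweeps = 120), quiet_profile(), cond1(),
                          channel_role = "contra", seed = 2)
  bb <- detect_bootstrap(ep_a, ep_b, n_boot = 99)
  expect_equal(bb$resample_size, 240L)

  # pooled epochs < 2 -> inconclusive
  empty <- ep; empty$accepted[] <- FALSE
  expect_equal(detect_bootstrap(empty, design = d, n_boot = 199,
                                seed = 1)$outcome, "inconclusive")
  expect_warning(detect_bootstrap(ep, design = d, n_boot = 50, seed = 1),
                 "n_boot")
})

test_that("polarity-flip resampling matches the naive algorithm in distribution", {
  # oracle: materialise the draws epoch-by-epoch; compare moments of the
  # resampled mean against the multinomial-counts shortcut
  set.seed(21)
  pool <- matrix(rnorm(12 * 40), 12)
  m <- 24
  naive <- replicate(400, {
    idx <- sample.int(12, m, replace = TRUE)
    signs <- sample(c(-1, 1), m, replace = TRUE)
    colMeans(signs * pool[idx, , drop = FALSE])
  })
  fast <- replicate(400, accdetect:::boot_signed_average(pool, m))
  expect_equal(mean(naive), mean(fast), tolerance = 0.01)
  expect_equal(sd(as.numeric(naive)), sd(as.numeric(fast)), tolerance = 0.05)
})

test_that("rms and bootstrap share the noise-floor denominator convention", {
  d <- small_design(sweeps = 2)
  pr <- quiet_profile(noise_rms_uv = 1)
  ep <- simulate_epochs(d, pr, cond1(), seed = 3)
  b <- detect_bootstrap(ep, design = d, n_boot = 99, seed = 1)
  avg <- average_epochs(ep)
  r_peak <- suppressWarnings(detect_rms(avg, peak_rms = TRUE))
  # same numerator (N1-P2) and denominator (noise-floor RMS) up to the
  # sqrt(2) convention of the peak-RMS reading
  expect_equal(b$statistic, r_peak$statistic * sqrt(2), tolerance = 1e-9)
})

test_that("plain-resample mode gives an uncertainty interval around the observed statistic", {
  d <- small_design(sweeps = 30)
  pr <- quiet_profile(noise_rms_uv = 2)
  ep <- simulate_epochs(d, pr, cond1(), seed = 11)
  b <- detect_bootstrap(ep, design = d, n_boot = 199, seed = 5,
                        null = "resample")
  # the observed statistic sits inside its own sampling interval
  expect_gt(b$statistic, b$ci_lower)
  expect_lt(b$statistic, b$ci_upper)
  expect_equal(b$outcome, "present")  # strong response: lower bound > 1
})
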