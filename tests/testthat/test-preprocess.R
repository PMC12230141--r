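test_that("band-pass magnitude response has the designed pass- and stop-bands", {
  d <- small_design(fs = 512)
  bp <- acc_bandpass(d)
  # DC and 50 Hz are in the stopbands (30 dB per pass by design)
  expect_lt(bp$response(0.2), 10^(-30 / 20) + 1e-3)
  expect_lt(bp$response(50), 10^(-30 / 20) + 1e-3)
  expect_gt(bp$response(10), 0.9)

  # a filtered sinusoid's amplitude matches the frequency-response oracle,
  # squared because the filter runs forward-backward
  t <- seq(0, 8, by = 1 / d$fs)
  for (f in c(10, 50)) {
    x <- sin(2 * pi * f * t)
    y <- accdetect:::filtfilt_padded(x, bp, d$fs)
    mid <- seq(round(length(y) * 0.3), round(length(y) * 0.7))
    gain <- (max(y[mid]) - min(y[mid])) / 2
    expect_equal(gain, bp$response(f)^2, tolerance = 0.02)
  }
})

test_that("referencing subtracts Cz and suppresses DC", {
  d <- small_design(fs = 512)
  n <- round(6 * d$fs)
  cont <- data.frame(Cz = rep(1, n), ipsi = rep(3, n), contra = rep(0.5, n))
  out <- reference_and_filter(cont, d)
  mid <- seq(round(n * 0.3), round(n * 0.7))
  # (ipsi - Cz) = 2 is pure DC: stopband leaves < 1% of it
  expect_lt(max(abs(out$ipsi[mid])), 0.02 * 2)
  expect_error(reference_and_filter(data.frame(ipsi = 1:10), d), "Cz")
  expect_error(reference_and_filter(data.frame(Cz = 1:10), d), "mastoid")
})

test_that("filtering is linear", {
  d <- small_design(fs = 256, sweeps = 2)
  set.seed(5)
  x <- matrix(rnorm(2 * d$n_samples), 2)
  ex <- acc_epochs(x, d); ey <- acc_epochs(x[2:1, ], d)
  fx <- filter_epochs(ex)$data
  fy <- filter_epochs(ey)$data
  combo <- acc_epochs(2 * x + 3 * x[2:1, ], d)
  expect_equal(filter_epochs(combo)$data, 2 * fx + 3 * fy, tolerance = 1e-8)
})

test_that("epoching cuts the right windows and baseline-corrects each epoch", {
  d <- small_design(fs = 256, sweeps = 120)
  fs <- d$fs
  n <- round(400 * fs)
  series <- rep(7, n)  # constant series
  events <- seq(1, by = 3, length.out = 120)
  ep <- epoch_and_baseline(series, events, d)
  expect_equal(nrow(ep$data), 120)
  expect_true(all(abs(ep$data) < 1e-12))  # constant minus its baseline

  # event too close to the start: epoch dropped and reported
  expect_message(
    ep2 <- epoch_and_baseline(series, c(0.05, events), d),
    "dropped 1 event")
  expect_equal(nrow(ep2$data), 120)
  expect_equal(attr(ep2, "dropped_events"), 0.05)

  # baseline mean is zero for arbitrary signals too
  set.seed(1)
  ep3 <- epoch_and_baseline(rnorm(n), events[1:10], d)
  base_idx <- which(d$time_s < 0)
  expect_true(all(abs(rowMeans(ep3$data[, base_idx])) < 1e-12))
})

test_that("2-SD RMS rejection implements the single-pass rule", {
  d <- small_design(fs = 128, sweeps = 120)
  # 119 unit-RMS epochs + one wild epoch: exactly the wild one goes
  set.seed(2)
  base <- matrix(rnorm(120 * d$n_samples), 120)
  base <- base / sqrt(rowMeans(base^2))
  base[50, ] <- base[50, ] * 50
  ep <- reject_artifacts(acc_epochs(base, d))
  expect_equal(which(!ep$accepted), 50)
  report <- attr(ep, "rejection_report")
  expect_equal(report$rms[1], 1, tolerance = 1e-9)
  expect_match(attr(report, "rule"), "2\\*sd")

  # identical epochs: SD of RMS is 0, nothing is rejected
  same <- matrix(1, 10, d$n_samples)
  expect_true(all(reject_artifacts(acc_epochs(same, small_design(fs = 128, sweeps = 10)))$accepted))

  # permutation invariance
  perm <- sample(120)
  ep_perm <- reject_artifacts(acc_epochs(base[perm, ], d))
  expect_equal(which(!ep_perm$accepted), match(50, perm))

  expect_error(reject_artifacts(acc_epochs(base[1, , drop = FALSE],
                                           small_design(fs = 128, sweeps = 2))),
               "at least 2")
})

test_that("rejection fraction on Gaussian epochs matches the empirical 2-SD tail", {
  d <- small_design(fs = 128, sweeps = 40)
  frac <- replicate(60, {
    x <- matrix(rnorm(40 * d$n_samples), 40)
    mean(!reject_artifacts(acc_epochs(x, d))$accepted)
  })
  # oracle: brute-force application of the mean + 2-SD rule to freshly drawn
  # RMS values at the same set size (RMS of m unit-Gaussian samples is
  # sqrt(chisq_m / m)), independent of the epoch pipeline
  m <- d$n_samples
  tail_rate <- mean(replicate(500, {
    rms <- sqrt(rchisq(40, m) / m)
    mean(rms > mean(rms) + 2 * sd(rms))
  }))
  expect_lt(abs(mean(frac) - tail_rate), 0.01)
})

test_that("averaging uses accepted epochs only and follows the sqrt(n) law", {
  d <- small_design(fs = 128, sweeps = 4)
  x <- matrix(rnorm(4 * d$n_samples), 4)
  ep <- acc_epochs(x, d, accepted = c(TRUE, TRUE, FALSE, TRUE))
  avg <- average_epochs(ep)
  expect_equal(avg$waveform, colMeans(x[c(1, 2, 4), ]))
  expect_equal(avg$n_accepted + avg$n_rejected, 4)
  # rejected epoch contents are irrelevant
  x2 <- x; x2[3, ] <- 1e6
  expect_equal(average_epochs(acc_epochs(x2, d, accepted = ep$accepted))$waveform,
               avg$waveform)

  # two opposite epochs cancel
  ep0 <- acc_epochs(rbind(x[1, ], -x[1, ]), d)
  expect_equal(average_epochs(ep0)$waveform, rep(0, d$n_samples))

  # zero accepted epochs -> inconclusive, no waveform
  none <- average_epochs(acc_epochs(x, d, accepted = rep(FALSE, 4)))
  expect_true(none$inconclusive)
  expect_null(none$waveform)

  # RMS of the average shrinks like 1/sqrt(n) for independent noise
  n_ep <- 16
  ratio <- replicate(100, {
    m <- matrix(rnorm(n_ep * 200), n_ep)
    dd <- acc_design(fs = 100, sweeps = n_ep, epoch_start_s = 0, epoch_end_s = 2)
    sqrt(mean(colMeans(m)^2)) / mean(sqrt(rowMeans(m^2)))
  })
  expect_equal(mean(ratio), 1 / sqrt(n_ep), tolerance = 0.02)
})
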