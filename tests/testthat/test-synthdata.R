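test_that("template morphology is controlled by its parameters", {
  d <- small_design()
  expect_equal(acc_template(d, 0, 0), rep(0, d$n_samples))

  w <- acc_template(d, 3, 2)
  expect_equal(max(w) - min(w), 5, tolerance = 0.01)
  # zero outside the response interval
  outside <- d$time_s < d$tone_onset_s | d$time_s > d$tone_onset_s + 0.4
  expect_true(all(w[outside] == 0))
  expect_error(acc_template(d, 3, 2, n1_lat_s = 1.3), "N1 window")

  # round-trip: injected latencies recovered within one sample
  pk <- find_peaks(w, d)
  expect_lt(abs(pk$n1_latency_s - 1.100), 1 / d$fs + 1e-12)
  expect_lt(abs(pk$p2_latency_s - 1.200), 1 / d$fs + 1e-12)
})

test_that("simulated epochs are reproducible and carry the embedded response", {
  d <- small_design()
  pr <- quiet_profile()
  ep1 <- simulate_epochs(d, pr, cond1(), seed = 42)
  ep2 <- simulate_epochs(d, pr, cond1(), seed = 42)
  expect_identical(ep1$data, ep2$data)
  expect_false(identical(ep1$data,
                         simulate_epochs(d, pr, cond1(), seed = 43)$data))

  # noiseless generation recovers the injected amplitude exactly
  pr0 <- quiet_profile(noise_rms_uv = 0)
  ep0 <- simulate_epochs(d, pr0, cond1(), seed = 1)
  avg <- average_epochs(ep0)
  amp <- pr0$acc_amp_at_max_snr_uv[["1000"]]
  tmpl <- acc_template(d, 0.6 * amp, 0.4 * amp)
  expect_equal(avg$waveform, tmpl, tolerance = 1e-12)
  expect_equal(find_peaks(avg)$n1p2_amp_uv, max(tmpl) - min(tmpl))

  expect_error(simulate_epochs(d, pr, list(frequency_hz = 2000, snr_db = 15,
                                           repetition = 1), seed = 1),
               "not in the design grid")
})

test_that("mean embedded response grows with SNR and shrinks with habituation", {
  d <- small_design(sweeps = 2)
  pr <- quiet_profile(noise_rms_uv = 0)
  amps <- vapply(sort(d$snr_levels_db), function(s) {
    avg <- average_epochs(simulate_epochs(d, pr, cond1(snr = s), seed = 1))
    find_peaks(avg)$n1p2_amp_uv
  }, numeric(1))
  expect_true(all(diff(amps) >= 0))

  a_rep2 <- find_peaks(average_epochs(
    simulate_epochs(d, pr, cond1(rep = 2), seed = 1)))$n1p2_amp_uv
  expect_equal(a_rep2 / amps[length(amps)], pr$habituation_factor,
               tolerance = 1e-6)

  # contralateral scaling
  a_contra <- find_peaks(average_epochs(
    simulate_epochs(d, pr, cond1(), channel_role = "contra",
                    seed = 1)))$n1p2_amp_uv
  expect_equal(a_contra / amps[length(amps)], pr$contra_scale, tolerance = 1e-6)
})

test_that("Monte-Carlo mean N1-P2 is non-decreasing in SNR under noise", {
  d <- small_design(fs = 128, sweeps = 12)
  pr <- participant_profile(artifact_rate = 0)
  levels <- sort(d$snr_levels_db)
  mean_amp <- vapply(levels, function(s) {
    mean(vapply(1:40, function(r) {
      # common random numbers across levels: same seed, same noise
      avg <- average_epochs(simulate_epochs(d, pr, cond1(snr = s), seed = r))
      find_peaks(avg)$n1p2_amp_uv
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_amp) >= 0))
})

test_that("dead-region suppression zeroes the response below the configured SNR", {
  d <- small_design(sweeps = 2)
  pr <- quiet_profile(noise_rms_uv = 0, dr_suppression_snr_db = 12)
  low <- average_epochs(simulate_epochs(d, pr, cond1(snr = 9), seed = 1))
  high <- average_epochs(simulate_epochs(d, pr, cond1(snr = 12), seed = 1))
  expect_equal(find_peaks(low)$n1p2_amp_uv, 0)
  expect_gt(find_peaks(high)$n1p2_amp_uv, 3)
})

test_that("cohort simulation produces the full grid, seeds, and opt-in attrition", {
  d <- small_design(fs = 128, sweeps = 4)
  co <- simulate_cohort(d, 1, seed = 1)
  expect_equal(nrow(co$manifest), 48)  # 2 freq x 6 snr x 2 rep x 2 channels
  expect_equal(sum(co$manifest$present), 48)
  expect_length(co$epochs, 48)
  expect_true(all(!duplicated(co$manifest$seed)))

  co2 <- simulate_cohort(d, 1, seed = 1)
  expect_identical(co$epochs[[1]]$data, co2$epochs[[1]]$data)

  # attrition marks recordings missing (both channels of the recording)
  co3 <- simulate_cohort(d, 2, attrition_fraction = 39 / 552, seed = 2)
  n_rec <- nrow(unique(co3$manifest[, c("participant", "frequency_hz",
                                        "snr_db", "repetition")]))
  n_dropped <- round(39 / 552 * n_rec)
  expect_equal(sum(co3$manifest$present), 2 * (n_rec - n_dropped))
  expect_length(co3$epochs, sum(co3$manifest$present))
})

test_that("staircase simulator converges and flags degenerate runs", {
  # near-deterministic listener descends from the start toward threshold
  s <- simulate_staircase(0, start_db = 16, psychometric_slope = 100, seed = 1)
  first_wrong <- which(!s$track$correct)[1]
  expect_true(all(diff(s$track$level[seq_len(first_wrong)]) <= 0))
  expect_false(s$flagged)

  # mean estimate near the Markov-chain equilibrium of the 4-down/2-up rule
  slope <- 2
  p_fun <- function(l) plogis(slope * (l - 0))
  eq <- staircase_equilibrium(p_fun, down = 4, up = 2)
  ests <- vapply(1:300, function(r) {
    simulate_staircase(0, start_db = 10, psychometric_slope = slope,
                       seed = r)$threshold_db
  }, numeric(1))
  expect_lt(abs(mean(ests) - eq), 2)

  # always-correct listener rides the floor and is flagged
  s2 <- simulate_staircase(-1000, start_db = 70, psychometric_slope = 100,
                           floor_db = 0, seed = 3)
  expect_true(s2$flagged)
  expect_lte(s2$threshold_db, 4)
})
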