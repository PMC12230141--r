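---
title: "Objective detection of the acoustic change complex: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Objective detection of the acoustic change complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accdetect)
```

## The problem

The acoustic change complex (ACC) is the cortical N1-P2 response evoked by a
change inside an ongoing sound — here, a pure tone appearing in ongoing
threshold-equalizing noise (TEN). Because the ACC can be recorded without a
behavioural response, it is a candidate objective substitute for the
behavioural TEN test used to screen for cochlear dead regions, where masked
thresholds more than 10 dB above both the TEN level and the absolute
threshold indicate a dead region, and an ACC threshold at or above 12 dB SNR
has been proposed as the electrophysiological analogue.

Deciding *whether a single recording contains an ACC* is the crux. This
package implements three decision rules operating on epoched EEG, an
ACC-threshold definition over an SNR ladder, the dead-region screens, and
the agreement statistics used to compare detection methods — all driven by a
synthetic-EEG generator so that every stage can be exercised and tested
without recorded data.

## The recording model

The default `acc_design()` encodes the study protocol: EEG at 2048 Hz,
masker onset at 0 s, tone onset at 1 s for 0.5 s, epochs from −0.1 to 2.5 s
(5325 samples; 2.6 s × 2048 Hz = 5324.8 is rounded, with a half-open
`[start, end)` sample convention throughout), 120 sweeps per condition, six
SNRs from 15 down to 0 dB in 3-dB steps, two tone frequencies (1 and
4 kHz), two repetitions, and ipsi/contralateral mastoid channels referenced
to Cz. N1 is the most negative sample 80–120 ms after tone onset
(1.080–1.120 s), P2 the most positive at 1.170–1.230 s; the "noise floor"
window is the same 80–230 ms span placed after the stimulus offset
(1.580–1.730 s).

### Preprocessing

`reference_and_filter()` subtracts Cz from each mastoid and applies the
1–30 Hz band-pass; `epoch_and_baseline()` cuts epochs and subtracts each
epoch's mean over [−0.1, 0) s; `reject_artifacts()` drops epochs whose RMS
exceeds `mean(RMS) + 2·SD(RMS)` in a single pass; `average_epochs()`
averages the survivors. Three choices here were genuinely open:

* **The filter.** A "3rd-order Chebyshev type-II band-pass, 1–30 Hz, 30 dB
  ripple" does not pin down one realisation. We cascade a 3rd-order
  type-II high-pass (stopband edge 1 Hz) with a 3rd-order type-II low-pass
  (stopband edge 30 Hz), each with 30 dB stopband attenuation, and apply
  the cascade forward–backward. Zero-phase filtering keeps the absolute
  N1/P2 windows valid (a causal filter would delay the peaks) at the price
  of squaring the magnitude response: stopband attenuation doubles to
  60 dB, and so does passband droop. A 3rd-order type-II low-pass whose
  *stopband* starts at 30 Hz rolls off from well below 30 Hz, so a narrow
  N1 deflection loses roughly a quarter of its peak-to-peak amplitude
  after zero-phase filtering. This droop is a property of the published
  filter specification, not of this implementation; the exact magnitude
  response is exposed via `acc_bandpass()$response()`. Epochs that arrive
  pre-cut (the synthetic path) are filtered per epoch with 1 s reflective
  edge padding.
* **The rejection rule.** "RMS larger than two standard deviations of their
  mean value" is read as `RMS > mean(RMS) + 2·SD(RMS)` over the epochs of
  one recording; the literal alternative (`RMS > 2·mean`) would almost
  never reject anything for homogeneous data. The rule text applied is
  recorded in the rejection report. Rejection runs once per recording (the
  two repetitions are never pooled for rejection).
* **Inconclusive propagation.** A recording whose epochs are all rejected
  yields no waveform; every detector returns `inconclusive` for it rather
  than a guess, and the threshold rule treats such cells as missing.

## The three detection methods

**RMS ratio.** `detect_rms()` computes the RMS of the averaged waveform
over 1.080–1.230 s divided by the RMS over 1.580–1.730 s and declares the
response present when the ratio is at least 1.5 (boundary inclusive). "RMS
of N1-P2 amplitude" is read as the RMS of the waveform segment spanning the
two peak windows, since the RMS of a two-point quantity is not well
defined; `peak_rms = TRUE` offers the |N1-P2|/√2 reading instead.

**Repetition SNR (BSA-style).** `detect_bsa()` takes the N1-P2 amplitudes
a₁, a₂ of the two repetitions and computes
`20·log10(mean(a₁,a₂)/SD(a₁,a₂))`, present when > 3 dB, on the dB scale as
literally printed; `scale = "linear"` applies the mean/SD ≥ 3 reading
instead. Identical amplitudes (SD = 0) give an infinite statistic and a
present outcome, logged. Note a structural liberality of this criterion:
peak-to-peak amplitudes of noise-only averages are positively biased and
therefore *repeatable*, so the statistic can exceed 3 dB without any
response. The synthetic cohorts reproduce the corresponding field
observation that this method yields the lowest thresholds of the three.

**Bootstrap.** `detect_bootstrap()` pools the accepted epochs of both
channels (240 for the full design), computes the observed statistic — N1-P2
amplitude of the pooled average over the noise-floor RMS of that average —
and compares it with a null distribution built from 499 resamples of
`resample_size` epochs drawn with replacement, each drawn epoch's polarity
flipped independently at random. The flip destroys the phase-locked
response while preserving the noise spectrum; plain with-replacement
resampling preserves the response and cannot form a null, which is why the
flip variant is the default (`null = "resample"` provides the plain variant,
whose interval is then read as the sampling uncertainty of the observed
statistic, present when its lower bound exceeds 1). The decision is
one-sided — present when the observed statistic exceeds the upper bound of
the null's central 95% interval — because only a response *larger* than
noise is meaningful. `resample_size` defaults to the pool size: drawing
more epochs than the pool holds makes the null narrower than the observed
statistic's sampling distribution and inflates the false-present rate.
Internally each resampled average is formed from multinomial draw counts
and binomial signed counts, which is distributionally identical to
materialising the draws and two orders of magnitude faster. The observed
exceedance rate on pure-noise recordings sits in the 2.5–5% range expected
for an empirical-quantile one-sided test at α = 0.05.

Per-ear and pooled bootstrap decisions are both available
(`bootstrap_pooling` in the pipeline config); the pipeline defaults to
per-ear decisions because thresholds are reported per ear.

## Threshold and dead-region rules

`estimate_threshold()` applies the definition literally: the threshold is
the lowest SNR L with the response present at L, present at L+3 dB, and
absent at L−3 dB, with off-grid clauses vacuous (0 dB can qualify without a
lower neighbour, 15 dB without an upper one). Non-monotone outcome patterns
get no smoothing — the lowest qualifying L wins, and a brute-force
evaluation over all 2⁶ patterns is the test oracle. Inconclusive or missing
cells make the clauses that would read them vacuous and flag the result.
`undetermined` is a first-class outcome and propagates to the agreement
stage as missing. `classify_dead_region()` applies the 12-dB SNR screen
(inclusive; undetermined thresholds give `NA`, never `FALSE`) and the
behavioural TEN rule (masked ≥ TEN + 10 **and** masked ≥ absolute + 10).

## Agreement statistics

`bland_altman()` returns bias, SD of differences, 95% limits of agreement
(bias ± 1.96·SD), a t-based CI for the bias and `LoA ± t·√(3·SD²/n)` for
each limit — the classical formulas, which the published tables do not
restate. With `repeated = TRUE` and a `subject` key the variance of
differences is corrected for replicate pairs under a constant true value:
one-way ANOVA of the differences on subject, corrected variance = within
mean square + between-subject component. `repeatability()` adds the
coefficient of repeatability, 2·SD of the test–retest differences.
`ccc()` implements Lin's concordance correlation with n-denominator
moments and a Fisher-z CI (a percentile bootstrap CI is available); the
epidemiology package the original analysis used is not a dependency here,
and the implementation is validated against hand arithmetic in the tests.
The pipeline pairs methods using only the first repetition of the RMS and
bootstrap thresholds and the repetition-free BSA threshold, and treats
ipsi/contra thresholds as repeated measurements keyed by participant.

## The synthetic generator

`simulate_epochs()` emulates one recording: 1/f-shaped Gaussian background
restricted to 1–30 Hz with a small 10-Hz alpha bump, scaled to the
profile's RMS; an ACC template (negative Gaussian deflection at 1.100 s,
FWHM 30 ms, 60% of the peak-to-peak; positive at 1.200 s, FWHM 50 ms, 40%)
jittered in latency per epoch; and artifact epochs drawn as 10× amplitude
noise bursts. The waveshape is invented — published figures show but do not
parameterise it. Amplitude follows
`max(amp_max − slope·(15 − SNR), 0) × habituation(repetition) ×
contra_scale(channel)`, forced to zero below a configurable SNR for
simulated dead-region ears.

Default profile parameters are free choices, not estimates of any recorded
dataset: 8 µV (1 kHz) and 6 µV (4 kHz) at 15 dB SNR, 0.3 µV/dB slope,
10 µV background RMS, habituation 0.8, contralateral scale 0.6, 5 ms
latency jitter, 5% artifact rate. They were calibrated once so that each
method's detection transition falls inside the 0–15 dB grid and per-method
thresholds land in the few-dB range reported for normal-hearing adults.
What the generator does *not* emulate: real scalp topography, drowsiness
drift, non-Gaussian artifact families (blinks, jaw EMG), correlated noise
across channels, or any coupling between behavioural and
electrophysiological thresholds beyond the profile parameters. Passing
tests therefore demonstrate the correctness and calibration of the
*analysis*, not the physiology of real recordings.

`simulate_staircase()` emulates the behavioural threshold procedures
(2-down/1-up, −4/+2 dB) with a logistic listener; the threshold read-out is
the mean of the last 4 reversal levels with stopping at 8 reversals or 60
trials (the protocol is silent on the read-out; the choice is audited via
the returned track, and capped or floor-riding runs are flagged). The test
oracle for its convergence is the stationary mean of the explicit Markov
chain over (level, consecutive-correct) states.

`simulate_cohort()` materialises the full (participant × frequency × SNR ×
repetition × channel) grid with per-cell seeds derived from one master
seed, draws mild between-subject variation, simulates behavioural
staircases, and applies attrition only on request.

## Numerical and reproducibility choices

* Fixed seeds give bit-identical outputs at every stage; the pipeline
  derives per-recording seeds from a single master seed via a rolling
  string hash kept below 2³¹.
* Peak picking uses raw extrema with earliest-sample tie-breaks;
  parabolic interpolation sits behind a flag, off by default.
* Noiseless generation followed by the unfiltered preprocessing path
  recovers the injected N1-P2 amplitude to well under 1%; with the
  band-pass in place the recovery is scaled by the documented filter
  droop (about 25% for the default template widths).
* Monte-Carlo checks in the tests use a reduced problem size — 256 Hz
  sampling and 60–120 sweeps — chosen to keep the full statistical suite
  runnable on a laptop CPU; monotonicity checks use common random numbers
  across SNR levels (the same noise realisations, only the embedded
  amplitude varies) so that 200 replicates resolve adjacent levels.
* Table outputs use CSV with missing values as empty cells, never
  sentinel numbers.

## Known limitations

* No EDF/BDF reader: stored data enter via the package's own epoch
  container or plain CSV of continuous channels (`read_recording()`).
* The BSA-style criterion's liberality on noise (above) means its
  thresholds — and any dead-region decision based on them alone — are
  optimistic; the pipeline's dead-region table is best read from the RMS
  and bootstrap screens.
* The repeated-measures variance correction assumes a constant true value
  per subject; ipsi/contra asymmetries violate it mildly, exactly as they
  do in the original analysis.
* Simulated hearing loss is a hard amplitude gate at the configured SNR,
  not a model of off-frequency listening.
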