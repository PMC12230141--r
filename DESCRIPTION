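Package: accdetect
Title: Objective Detection of the Acoustic Change Complex in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for objective detection of the
    acoustic change complex (ACC), the cortical auditory evoked response
    elicited by a tone appearing in ongoing threshold-equalizing noise.
    Provides a synthetic epoched-EEG generator emulating a multi-condition
    ACC study design, preprocessing (mastoid-Cz referencing, zero-phase
    Chebyshev type-II band-pass filtering, epoching, baseline correction,
    RMS-based artifact rejection, averaging), N1/P2 peak measurement, three
    response-detection methods (RMS signal-to-noise-floor ratio, repetition
    SNR, and a polarity-flip bootstrap null), ACC-threshold estimation over
    an SNR grid, cochlear dead-region screening rules, adaptive-staircase
    psychophysics simulation, and method-agreement statistics (Bland-Altman
    limits of agreement with confidence intervals, coefficient of
    repeatability, Lin's concordance correlation coefficient).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
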