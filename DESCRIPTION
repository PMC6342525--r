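Package: sleeplfp
Title: NREM Sleep LFP Analysis: Spectra, Spindles, Slow Oscillations and
    Phase Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for local field potential (LFP) and EEG
    recordings of non-rapid-eye-movement sleep (NREMS). Computes
    normalized power spectra and band powers (slow-oscillation, delta,
    sigma), detects discrete sleep spindles from the 9-16 Hz squared-power
    envelope, detects slow-oscillation cycles as trough-to-peak half-wave
    pairs on the 2 Hz low-passed signal, phase-locks spindle onsets to the
    slow oscillation via the Hilbert transform, and quantifies delta-power
    time courses in equal-epoch quantile bins. Ships a ground-truth
    synthetic LFP generator (1/f background, slow-oscillation and delta
    components, waxing-waning spindle bursts with a configurable
    onset-phase preference) so every stage is verifiable without recorded
    data. All user-facing functions take and return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
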