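Package: prestim
Title: Pre-Stimulus Oscillatory Predictors of Saccadic Reaction Time
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for linking pre-stimulus magnetoencephalographic (MEG)
    oscillatory amplitude and phase to saccadic reaction-time variability.
    Provides a synthetic-data generator with injected amplitude-RT coupling
    (trial schedules with a non-aging foreperiod, dipole sources in a
    spherical head model, EOG traces), Savitzky-Golay based saccade
    detection and trial exclusion, a reaction-time correction cascade with
    a variance-accounting ledger, a scalar (SAM-style) beamformer with
    correlational source imaging, virtual-electrode Hilbert time-frequency
    analysis, a quintile inter-trial-coherence bootstrap, and group-level
    permutation and FDR inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
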