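Package: eegbench
Title: Simulation Bench for Neonatal EEG Acquisition Quality Assessment
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A software test bench for assessing EEG acquisition systems and
    electrodes without human participants. Generates synthetic neonatal EEG
    epochs, propagates them through skin-electrode equivalent-circuit
    impedance models and a non-ideal differential acquisition chain (input
    loading, common-mode to differential conversion by impedance mismatch,
    finite CMRR, amplifier noise, ADC quantization), and scores the received
    signals with Pearson correlation, RMS signal-to-noise ratio and 50 Hz
    power-line bin amplitude, summarised as mean with 95% confidence
    intervals across epochs. Includes skin-electrode impedance sweep fitting
    (parallel RC extraction), published wet/dry electrode presets, and a
    config-driven command-line bench runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'electrode-models.R'
    'quality-metrics.R'
    'synthetic-eeg.R'
    'acquisition-chain.R'
    'bench-cli.R'
    'eegbench-package.R'
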