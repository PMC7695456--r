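Package: optodetect
Title: Analysis Pipeline for All-Optical Perceptual Detection Experiments
Version: 0.1.0
Authors@R: person("Opto", "Detect", email = "maintainer@optodetect.org",
    role = c("aut", "cre"))
Description: Tools for analysing two-photon all-optical detection
    experiments in which ensembles of cortical neurons are photostimulated
    while an animal reports detection by licking. Implements go/catch trial
    scoring with signal-detection metrics, conversion of ROI fluorescence
    into trial-wise dF/sigmaF responses with neuropil subtraction and
    photostimulation-artefact exclusion, cross-validated calibration of
    activation/suppression thresholds to a fixed false-positive rate,
    3D target-zone classification of neurons, hit:miss matched network
    metrics, log-normal psychometric curve fitting with fixed lapse and
    guess rates, and cross-validated prediction of behaviour from neural
    predictors. A seeded synthetic-session generator with ground-truth
    bookkeeping makes every stage testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
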