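Package: raad
Title: Robust Anomaly-Beat Detection in Multi-Lead ECG with Artifacts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects anomalous heartbeats (e.g. premature ventricular
    contractions) in single- and multi-lead electrocardiograms while staying
    robust to common recording artifacts such as baseline wander, powerline
    interference, muscle tremor and motion.  The pipeline combines zero-phase
    Butterworth band-pass preprocessing, variable-length motif discovery with
    a minimum-description-length bitsave score to rank lead cleanliness and
    isolate normal beats, clinically parameterised PQRST delineation, and a
    segment-constrained partial dynamic-time-warping beat comparison.  Also
    provides the evaluation machinery used for beat-level detector assessment
    (overlap criteria, accuracy-on-detection, sensitivity, specificity,
    positive predictive value, false-alarm rate) and a seeded synthetic ECG
    generator with ground-truth fiducials, artifact injection and PVC-like
    anomalous beats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
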