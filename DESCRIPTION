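Package: rnfltcorrect
Title: Artifact Detection and Correction for Retinal Nerve Fiber Layer
    Thickness Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for working with peripapillary retinal nerve fiber layer
    thickness (RNFLT) maps from optical coherence tomography in glaucoma.
    Detects segmentation-failure artifacts (values below the 50 micrometer
    measurement floor), quantifies map quality by artifact ratio, extracts
    circumpapillary circle-scan profiles, and corrects artifact regions with
    a compact convolutional encoder-decoder trained on pseudo-artifact pairs
    built by transplanting artifact patterns from low-quality donor maps onto
    high-quality maps. Includes a synthetic cohort generator (thickness maps,
    artifacts, linked visual-field series), artifact-ratio-stratified
    evaluation of correction accuracy, and a clinical-utility harness:
    visual-field reliability filtering, OCT-VF pairing, structure-function
    prediction, trend-based progression criteria, patient-level
    cross-validation and bootstrap comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    pROC,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
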