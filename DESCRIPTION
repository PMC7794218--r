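Package: thermofly
Title: Thermoresponsive Locomotor Behavior, Calcium Imaging and
    Electrophysiology Analysis for Drosophila Open-Field Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for quantifying thermoresponsive motor
    behavior of freely walking Drosophila and the neuronal measurements that
    accompany it.  Provides a two-state (walk/pause) renewal-process
    simulator of open-field trajectories with Weibull-distributed pauses and
    a mechanical-startle stimulus; activity classification, bout and
    inter-bout-interval segmentation, and locomotor summary metrics; a
    Weibull shape-factor (kappa) burstiness fit to the inter-bout-interval
    distribution; GCaMP delta-F/F0 ramp-response and CaMPARI red/green
    photoconversion quantification from image stacks; current-clamp spike,
    f-I, passive-property and burst feature extraction together with a
    generalized Henderson liquid-junction-potential calculator; and a
    statistical gate that selects parametric or non-parametric tests and
    applies a two-control significance rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    fitdistrplus,
    jsonlite,
    multcomp,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
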