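Package: patchkit
Title: Signal Decoding for a Skin-Interactive Resistive Sensor Patch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a thin, size-cuttable
    resistive sensor patch worn on the skin. Models the voltage-divider
    transduction and ADC quantization of a multi-node piezoresistive array,
    calibrates per-node fabrication deviations, estimates body-surface
    curvature from ADC readings via an empirical linear law, decodes
    32 finger-binary gestures from wrist deformation maps through K-means
    vector quantization and core-line position/depth rules, evaluates
    single-finger classification with confusion-matrix metrics, and
    predicts the post-attachment signal settling transient with a small
    feedforward network trained by AdaGrad on mean absolute error.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
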