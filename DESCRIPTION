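Package: oromotor
Title: Analysis of Orofacial Movements, Fiber Photometry and Premotor Circuit Tracing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative analysis of rodent licking and lapping
    behaviour and its neural correlates: isosbestic-corrected fiber-photometry
    dF/F on a common 120 Hz analysis grid, post-processing of markerless
    pose-estimation tracks of the jaw and tongue (scale-bar calibration,
    Savitzky-Golay smoothing, likelihood gating, baseline normalization),
    lick-onset detection with bout segmentation and frequency estimation,
    lagged lick-calcium correlation curves with a circular-shuffle null and a
    paired per-animal test, classification of optogenetically evoked jaw
    movements as transient, sustained or rhythmic, and quantification of
    monosynaptic rabies-tracing input maps (per-region fractions, laterality
    bias, seeding efficiency). A deterministic synthetic-session generator
    with known ground truth supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
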