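Package: panoquant
Title: Quantification and Colocalization of Immunofluorescence Signals on
    Whole-Section Panoramic Images
Version: 0.1.0
Authors@R:
    person("Panoquant", "Developers", email = "panoquant@example.org",
           role = c("aut", "cre"))
Description: Pixel-based quantification of immunofluorescence (IF) staining on
    8-bit whole-section panoramic images of serial histological sections.
    Builds whole-section and tissue-compartment masks by lighten/darken pixel
    blending and morphological closing, determines the IF signal threshold
    separating true signal from autofluorescence by a regression scan over
    candidate binary thresholds, quantifies expression domains from grey-value
    histograms, summarizes spatial gradients as calibrated top-down plot
    profiles, and colocalizes multiple markers across serial sections with
    simple and multiple linear regression, sixth-order polynomial refinement,
    virtual knockout of individual predictors, and DAPI-based serial-section
    compatibility tables. A seeded synthetic-data generator produces
    gingiva-like panoramas with ground truth so the whole pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    png,
    jsonlite,
    stats,
    utils,
    withr,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
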