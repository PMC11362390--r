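Package: speckleFlow
Title: Laser Speckle Contrast Imaging Simulation and Perfusion
    Quantification
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative laser speckle contrast imaging (LSCI)
    of tissue perfusion. Simulates time-integrated dynamic speckle image
    stacks from flow phantoms with a closed-form contrast oracle, computes
    windowed spatial speckle contrast (sigma/mu) and laser speckle
    perfusion unit (LSPU) maps, extracts region-of-interest time series,
    derives Youden-index cut-offs separating ischemic from well-perfused
    tissue, fits the logarithmic LSPU-lactate calibration, emulates a
    porcine bowel-loop ischemia study design for end-to-end testing, and
    quantifies inter-observer agreement in watershed placement with
    Cohen's kappa.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    tiff,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse,
    knitr
Config/testthat/edition: 3
biocViews: Software, Visualization, Preprocessing
RoxygenNote: 7.3.3
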