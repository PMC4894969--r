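Package: cellmotion
Title: Quantitative Analysis of Cell Shape Volatility, Focal Adhesion
    Dynamics, Cortical Signals and AFM Elasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the morphodynamics of migrating cells from
    time-lapse microscopy and atomic force microscopy (AFM) data. Implements
    the shape-volatility statistic (standard deviation of relative
    aspect-ratio changes), migration speed and directional persistence,
    circular statistics for chemotaxis endpoints (Rayleigh test), a TIRF
    focal-adhesion pipeline (median filtering, Otsu segmentation,
    morphological cleanup, overlap-based track linking, the 10 percent
    stability rule, mask autocorrelation with double-exponential decay
    fitting, and semi-logarithmic assembly/disassembly rates), cortical
    signal metrics (edge-positive fraction, edge-distance intensity
    profiles, kymographs and protrusion periodicity), and Young's modulus
    estimation from AFM force curves with the Sneddon conical-indenter
    model. A synthetic-data module generates every input with recorded
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
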