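Package: birtrack
Title: Beam-Induced Reorientation Analysis for Electron-Diffraction Dose Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify beam-induced reorientation (BIR) of molecular
    nanocrystals in microcrystal electron diffraction (MicroED/3DED) dose
    series. Provides Bragg spot detection and per-reflection intensity
    tracing with derivative-profile fluctuation metrics, k-means
    classification of reflection traces by excitation epoch, symmetry
    disambiguation and outlier rejection of per-frame orientation-matrix
    series with net rotation axis/angle decomposition and crystal-quake
    detection, and bend-contour seismogram (kymograph) analysis of
    imaging-mode stacks. A synthetic dose-series simulator (warping-crystal
    model with resolution-dependent intensity decay) supplies ground truth
    for every analysis stage. Reads and writes MRC2014 stacks and SMV (ADSC)
    image series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
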