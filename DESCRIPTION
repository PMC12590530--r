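Package: nanomech
Title: Nanomechanical Fingerprinting of Fibrotic Tissue from AFM Force Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving atomic-force-microscopy (AFM) based
    nanomechanical fingerprints of pulmonary fibrosis. Covers the full
    in-silico pipeline: simulation of force-volume maps with known ground
    truth, calibration and contact-point detection of force-displacement
    curves, per-curve Young's modulus estimation under the Sneddon conical
    indentation model, per-specimen elasticity spectra with lower/higher
    elasticity peak (LEP/HEP) mixture decomposition and heterogeneity
    metrics, collagen I/III quantification from polarized picrosirius-red
    image pairs, second-harmonic-generation frame averaging, the study's
    statistical layer (median centering, ROUT outlier removal, exact
    small-n Spearman correlation, group tests, delta-delta-Ct), and a
    specimen-grouped cross-validated kernel classifier fusing optical and
    nanomechanical features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
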