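Package: resp4d
Title: Respiratory Signal Extraction and Retrospective Phase Sorting for
    Cine CT with a Frame-Mounted Fiducial Device
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to recover a respiratory signal from cine-mode axial CT
    images of a stereotactic body frame fitted with a moving-wire add-on
    device, and to sort the images retrospectively into respiratory bins.
    Includes a phantom simulator that renders synthetic cine studies of the
    device with known ground-truth motion (sinusoidal and shark-fin
    waveforms), sub-pixel wire cross-section detection and tracking, the
    lever-arm geometry linking wire displacement at a slice plane to the
    displacement of the abdominal central piece, sinusoid fitting with
    residual-based parameter uncertainties, and phase- or amplitude-based
    binning of frames into per-phase volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
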