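Package: scosr
Title: Multi-Channel Speckle Contrast Optical Spectroscopy Processing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Processing chain for multi-channel speckle contrast optical
    spectroscopy (SCOS) measurements of cerebral blood flow: synthetic
    speckle frame generation with realistic camera noise, dark correction
    and windowed statistics, noise-corrected fundamental contrast with
    shot, read, quantization and heterogeneity terms, optical density and
    relative blood-flow-index time courses, photon-transfer-curve gain
    calibration, channel-space statistics (quality control, short-separation
    and common-mode regression, filtering, block averaging, group tests),
    and Tikhonov-regularized image reconstruction on a toy sensitivity
    model. Includes the canonical 7-source / 17-detector high-density probe
    geometry and a temporal-multiplexing schedule model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
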