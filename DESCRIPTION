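Package: penkit
Title: Kinetics, Imaging and FRAP Analysis for Compartmentalised PEN DNA Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying polymerase-exonuclease-nickase (PEN) DNA
    reaction networks hosted in proteinosome microcompartments. Provides a
    mechanistic two-compartment reaction simulator and synthetic microscopy /
    FRAP generators with ground truth; watershed-based proteinosome
    segmentation and per-droplet time-series extraction; autocatalytic rate
    extraction via a Gaussian fit to the first differences followed by a
    windowed logistic fit; FRAP recovery fitting with diffusion-coefficient
    and immobile-fraction estimation; partition-coefficient and
    proteinosome-count calibration; and a seeded end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    minpack.lm,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
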