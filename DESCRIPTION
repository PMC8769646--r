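Package: phagolapse
Title: Simulation and Quantification of Phagosome Maturation Kinetics in
    Time-Lapse Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of phagosome maturation in
    multi-channel time-lapse fluorescence microscopy, modeled on assays of
    apoptotic-cell clearance in C. elegans embryos: ROI-based relative
    intensity of the phagosomal lumen and surface, a ratiometric GFP/mCherry
    acidification index, full-width-at-half-maximum diameter tracking of the
    engulfed-corpse nucleus, event-time statistics (engulfment duration,
    phagosome lifespan, fusion onset with censoring), and puncta detection
    with colocalization percentages.  A stochastic simulator of vesicle
    (autophagosome) recruitment and fusion kinetics, membrane topology,
    luminal pH decline, and pH-dependent fluorophore photophysics renders
    synthetic ground-truth image stacks so every measurement can be
    validated without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
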