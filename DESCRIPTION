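Package: nichescape
Title: Realized-Niche Overlap, Envelope Distribution Models and Ancestral
    Climatic Tolerances
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study climatic niche evolution across a clade: derivation
    of bioclim-style seasonal predictors from monthly environmental grids,
    principal-component reduction of environmental space, boxcar (Bioclim)
    envelope distribution models, occupancy-corrected kernel density grids in
    two-dimensional PC space with Schoener's D overlap and niche equivalency /
    background-similarity randomization tests, predicted niche occupancy (PNO)
    profiles, and generalized-least-squares reconstruction of ancestral
    climatic tolerances on calibrated ultrametric trees under Brownian motion.
    Includes a synthetic-data generator producing seasonal raster stacks,
    clade occurrence sets with controllable niche structure, and calibrated
    tree fixtures, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    geosphere,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite
Config/testthat/edition: 3
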