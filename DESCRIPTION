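Package: poremorph
Title: Stereological Pore Morphometry for Porous Scaffolds and Foams
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies 2D pore structure in micrographs of porous
    biomaterials such as tissue-engineering scaffolds and space-holder
    metal foams. Provides FFT band-pass pre-filtering and manual
    thresholding, external contour extraction, porosity, per-pore size
    (equivalent-circle diameter and the largest-sphere-through-pore
    radius found by a two-stage inscribed-circle grid search), ISO
    9276-6 shape factors (circularity, rotating-extent aspect ratio)
    and a curvature-based waviness (convex boundary fraction) computed
    on Fourier-smoothed contours, territory-based local area fractions
    with homogeneity colour maps, and radial ring-band profiles. A
    deterministic synthetic-shape generator with closed-form ground
    truths (overlapping-circle pores, regular polygons, half-ellipse
    horseshoes, mesh grids) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    stats,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage,
    optparse
Config/testthat/edition: 3
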