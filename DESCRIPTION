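Package: tjmesh
Title: Quantitative Analysis of Tight-Junction Meshworks from
    Super-Resolution Images
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to classify tight-junction (TJ) meshworks formed by
    claudins in STED-like super-resolution images and to quantify claudin
    segregation and paracellular ion permeability. Implements gray-level
    co-occurrence (Haralick) texture features, multiscale ridge (tubularity)
    segmentation with skeleton and mesh-size morphometrics, hierarchical
    classification of image-derived feature tables, Costes-thresholded
    Pearson colocalization, Gaussian line-profile strand-width (FWHM)
    measurement, Goldman-Hodgkin-Katz dilution-potential permeability
    analysis, and spectral FRET unmixing, together with a seeded synthetic
    image and measurement generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    cluster,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
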