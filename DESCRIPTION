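Package: haratex
Title: Haralick Texture Analysis for Biofilm Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grey-level co-occurrence matrix (GLCM) texture quantification for
    greyscale micrographs of bacterial biofilm surfaces. Computes the five
    Haralick statistics (contrast, correlation, energy, homogeneity, entropy)
    at the four standard directional offsets with mean/standard-deviation
    summaries, spatially resolved sliding-window texture maps with red-green
    feature overlays, two-channel cross-modality composites, condition
    comparison tables, and a noise-injection robustness test. Includes a
    seeded synthetic micrograph generator that emulates fields of rod-shaped
    cells with an optional smooth extracellular-matrix veil under optical,
    SEM and scanning-helium-microscope style imaging profiles, so the whole
    pipeline is testable without access to original image data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
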