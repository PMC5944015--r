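Package: shootgraph
Title: Graph-Based Holistic and Component Phenotyping of Maize Shoots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes holistic and component phenotypes of single maize
    plants from side-view greenhouse image sequences. Segments the plant
    from a fixed background (frame differencing, green-pixel
    superimposition and HSV thresholding), reduces the binary mask to a
    pruned one-pixel skeleton, builds a typed plant graph with base, tip
    and junction nodes, and detects individual leaves and the stem.
    Derives convex-hull based holistic traits (bi-angular convex-hull
    area ratio, plant aspect ratio, plant aerial density), per-leaf
    geometry from fitted polynomial leaf curves (leaf length, junction-tip
    distance, apex and mid-leaf curvature, leaf-junction angle, integral
    leaf-skeleton area) and the stem angle. Includes a deterministic
    synthetic plant image generator with exact ground truth, readers and
    writers for UNL-CPPD style ground-truth XML, plant-level leaf
    detection accuracy scoring, and per-day fixed-effects models of block
    and genotype effects on phenotype trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
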