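Package: fibrosynth
Title: Adaptive Exemplar-Based Synthesis and Pore-Network Analysis of
    Fibrous Porous Microstructures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates new three-dimensional realizations of fibrous porous
    microstructures (such as meniscal collagen networks) from a single binary
    exemplar volume. A double distance map turns the binary image into a
    smoothly interpolatable grayscale field; a diversified patch dataset is
    built from seven geometric transformations of that field; and new volumes
    are assembled by overlap-matched patch quilting with distance-weighted
    blending. Reconstructions can be steered towards target porosity,
    specific surface area and maximum pore size through a normalized feature
    space. The package also extracts pore networks by marker-based watershed
    segmentation, solves Hagen-Poiseuille network flow for directional Darcy
    permeability, and evaluates empirical porosity-permeability and
    porosity-modulus correlations, including porosity maps inferred from CT
    images. A built-in fibrous phantom generator makes the whole pipeline
    testable without micro-CT data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    igraph,
    jsonlite,
    tiff,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
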