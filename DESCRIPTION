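Package: neurotexfusion
Title: Texture-Descriptor Fusion Pipeline for Brain-MRI Tumor Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A reproducible pipeline for four-class brain-MRI tumor
    classification from 2-D grayscale slices: K-means intensity segmentation
    of the region of interest with PSNR/RMSE fidelity scoring, three
    handcrafted texture descriptors (gray-level co-occurrence matrix
    statistics, local ternary patterns, and a grayscale color coherence
    vector), leakage-safe standardization plus principal-component fusion of
    the descriptors fitted on training data only, and a small
    densely-connected classifier head trained with Adam, dropout and early
    stopping.  A seeded phantom generator produces four-class synthetic
    brain-like images with class-distinct texture statistics so the entire
    pipeline runs and is testable without any external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    igraph,
    png,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
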