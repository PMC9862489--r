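Package: wingcoi
Title: Wing Geometric Morphometrics and COI Barcode Divergence for
    Mosquito Species Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A dual species-identification toolkit for mosquitoes,
    built around the two workflows entomologists use when morphological
    keys fail: landmark-based wing geometric morphometrics (Generalized
    Procrustes superimposition, partial-warp shape variables, canonical
    discrimination with Mahalanobis distances, permutation tests, and
    leave-one-out reclassification) and COI DNA barcoding
    (Kimura-2-parameter divergences, barcoding-gap detection, and
    neighbor-joining trees with bootstrap support). Includes synthetic
    generators for wing-landmark and barcode datasets so every stage of
    both pipelines can be exercised end to end without external data.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    rlang,
    seqinr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
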