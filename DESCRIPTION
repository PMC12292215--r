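Package: tpmsdesign
Title: Design and Multi-Objective Optimization of Cylindrical TPMS Bone-Implant Lattices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end toolkit for designing cylindrical shell-type
    triply periodic minimal surface (TPMS) lattices for bone-implant
    applications. Generates Gyroid, Schwarz-Diamond and Split-P lattices
    from implicit surfaces (voxelization, marching-tetrahedra isosurface
    extraction, binary STL export) and computes geometric descriptors
    (relative density, surface area, SA/VR, porosity). Enumerates
    full-factorial design spaces with aspect-ratio filtering and
    implant-size classification, extracts mechanical metrics from
    compression curves (ultimate stress, energy absorption, modulus,
    yield, plateau), evaluates the Johnson-Cook failure-strain law, and
    simulates FEA-like property tables for offline testing. A multi-output
    feed-forward neural-network surrogate (Adam/MSE) maps design features
    to properties; a from-scratch NSGA-II maximizes ultimate stress,
    energy absorption and SA/VR per implant-size group with
    relative-density filtering; one-factor-at-a-time sensitivity and
    exact/sampled Shapley attribution explain any fitted predictor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
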