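Package: ismflux
Title: Single-Molecule Localization by Orbital Doughnut Scanning with a
    SPAD Array Detector
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for MINFLUX-style single-molecule
    localization with a doughnut-shaped excitation beam scanned on a circular
    targeted coordinate pattern and imaged in descanned mode onto a small
    single-photon detector array. Provides a parametric model of the molecule
    detection functions (MDFs), multinomial maximum-likelihood position
    estimation from photon-count tensors, Fisher-information and Cramer-Rao
    bound maps over the field of view, a Poisson photon-trace generator with
    DNA-PAINT-like blinking, an event-detection and filtering pipeline with
    three-segment localization, and orbit self-calibration from the data
    themselves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    withr
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
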