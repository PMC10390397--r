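Package: sdexa
Title: Scout-Based Dual-Energy Absorptiometry Simulation and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for scout-based dual-energy
    absorptiometry (SDEXA) of the lumbar spine. Generates digital spine
    phantoms with known water and hydroxyapatite densities, simulates
    virtual monoenergetic CT volumes and low-dose two-channel spectral
    scout projections with Poisson counting noise, performs material
    decomposition in the image domain (volumetric bone mineral density)
    and the projection domain (areal bone mineral density), reduces the
    anticorrelated decomposition noise with a patch-dictionary denoiser
    driven by a minimum-noise image and a local linear back-transform,
    forward-projects volumes and masks in fan-beam scout geometry,
    registers projected to measured maps, and reproduces the
    regression, t-test and ROC classification analyses used for
    opportunistic osteoporosis screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    RNifti,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
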