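Package: octapipe
Title: Spectral-Domain OCT Angiography Simulation, Reconstruction and Vessel Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete spectral-domain optical coherence tomography angiography
    (SD-OCTA) image-computation pipeline for small-animal retinal imaging,
    driven by a synthetic retina phantom with full ground truth. Covers
    spectral-fringe synthesis and k-space reconstruction, complex-difference
    flow contrast, gradient-based retinal layer segmentation with plexus slab
    masks, en-face projection, windowed vessel area density and skeleton-based
    fragmentation metrics, and the longitudinal statistics (Greenhouse-Geisser
    corrected repeated-measures ANOVA, Tukey post hoc tests, linear trends)
    used to characterise progressive deep-plexus capillary loss in retinal
    degeneration models such as the RCS rat.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    EBImage,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    optparse,
    withr
Config/testthat/edition: 3
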