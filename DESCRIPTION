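Package: blastopack
Title: Particle-Based Simulation and Image Quantification of Cavity-Driven
    Cell Packing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how an expanding embryonic cavity (blastocoel)
    compresses the surrounding cell layer. Provides a two-dimensional
    particle-based tissue model with an anharmonic pairwise potential, a fixed
    outer ring and a growing central repulsive cavity; image-derived
    quantifications used in developmental mechanics (cell packing index,
    intercellular space, nuclear-to-cytoplasmic protein ratio, background-
    subtracted ROI integrated density, Pearson and Manders overlap
    colocalization); ground-truthed synthetic image and measurement
    generators; and the normality-gated group-comparison statistics commonly
    used alongside these measurements. All results are returned as tibbles
    with broom-style tidiers and ggplot2 autoplot methods.
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
    jsonlite,
    multcomp,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
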