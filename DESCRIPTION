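Package: biofilmorph
Title: Quantification of 3D Biofilm Architecture from Confocal Image Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the three-dimensional architecture of
    surface-attached microbial biofilms from calibrated confocal image
    stacks: biovolume, substratum and cross-sectional coverage, surface
    area to volume ratio, mean thickness, roughness fluctuation
    coefficient, box-counting boundary fractal dimension, the Hopkins
    spatial aggregation index and a volume-threshold aggregation
    coefficient, together with substrate roughness descriptors (RMS
    roughness, roughness factor, line profiles), growth-curve and
    roughness-biovolume model fitting, and a synthetic confocal-stack
    generator with exact ground truth for validating every stage of the
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    generics,
    igraph,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    withr
Suggests:
    optparse,
    purrr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
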