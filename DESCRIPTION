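Package: npquant
Title: Quantitative Analysis of Nucleus Pulposus Cell Mechanics, Organization, and Matrix Production
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying nucleus pulposus (NP) cell-matrix interaction
    experiments on soft gel substrates. Implements Hertz spherical-contact
    analysis of AFM force-indentation curves with contact-point extrapolation,
    indentation-grid processing and cell-height measurement; estimation of cell
    numbers in three-dimensional multi-cell clusters from confocal stacks by
    integrated nuclear fluorescence, with cluster morphometrics
    (height, projected area, maximum in-plane dimension); reduction of DMMB
    sulfated-glycosaminoglycan and DNA plate-reader data to normalized
    cumulative production; one- and two-factor ANOVA with Tukey's HSD built
    from sums of squares; and seeded synthetic-data generators (force curves,
    image stacks, assay plates) that provide ground truth for validating every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    optparse
Config/testthat/edition: 3
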