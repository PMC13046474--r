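Package: tissuemech
Title: Tissue Mechanics and Expression Quantification for Developing Brain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of mechano-chemical measurements in developing
    brain tissue. Fits atomic force microscopy (AFM) force-distance curves to the
    Hertz spherical-contact model to recover the reduced apparent elastic modulus K,
    assembles per-point fits into stiffness maps with region-of-interest voting and
    regional medians, fits a ramp-corrected standard-linear-solid creep model to
    force-clamp indentation data, quantifies in situ hybridization puncta by
    area-fraction particle analysis with normalized-expression ratios, measures
    relative nuclear density and optic-tract elongation from image masks,
    post-processes reconstructed 3D traction displacement/force fields (neighbour
    and z-score outlier filters, vector-magnitude extrema, strain energy), and
    provides the matched group statistics (ratio-paired t, nested t, rank tests,
    Kruskal-Wallis with Dunn post hoc). A synthetic-data module generates every
    input class with known ground truth for end-to-end recovery testing.
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
    EBImage,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
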