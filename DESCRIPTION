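Package: capmorph
Title: Morphometry of Brain Capillary Ultrastructure and Neurovascular-Unit Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of brain-capillary ultrastructure and
    molecular markers in experimental subarachnoid hemorrhage (SAH).
    Computes annotation-based morphometry of electron-micrograph capillary
    cross-sections (shape descriptors, volume fractions, grid-overlay basal
    lamina thickness, tight-junction tortuosity, pericyte and astrocyte
    coverage, electron-lucent "hole" area), threshold-based 3-D
    colocalization statistics (Costes automatic thresholds, Pearson
    correlation, percent material colocalized), molecular quantification
    (2^-ddCT relative expression, immunoblot densitometry, zymogram
    activity), six-segment SAH grading with inclusion filtering, and
    animal-level group comparison with FDR-corrected pairwise tests.
    Includes a synthetic phantom generator with known ground truth so the
    whole pipeline is testable without raw micrographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
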