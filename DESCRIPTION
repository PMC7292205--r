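Package: coodx
Title: Cell-of-Origin Subtyping of Diffuse Large B-Cell Lymphoma from
    qPCR Gene Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a qPCR-based 32-gene cell-of-origin (COO) assay for
    diffuse large B-cell lymphoma (DLBCL): replicate aggregation and -dCt
    normalization of Ct triplicates against the housekeeping genes IPO8,
    PGK1 and TFRC; recursive feature elimination with a linear
    support-vector machine to derive the gene panel; a calibrated linear
    classifier assigning ABC, GCB or unclassified subtypes with a
    probability call threshold; the Hans immunohistochemistry surrogate;
    agreement statistics (overall, positive and negative percent agreement
    with Wilson score intervals, exact McNemar comparison); complete-linkage
    clustering on Pearson distance; and Kaplan-Meier / log-rank outcome
    stratification. A synthetic-cohort generator provides fixtures with the
    statistical structure the assay assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    purrr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
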