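Package: estarray
Title: Integrated EST Digital-Northern and Microarray Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrates in silico gene expression estimates derived from EST
    library composition with experimental microarray and GeneChip expression
    values. Tentative consensus sequences (TCs) are selected by a three-state
    (MUST / MUST NOT / MAY) cDNA-library filter, scored with the Stekel et al.
    (2000) logarithmic likelihood ratio R, joined to platform reporters and
    their expression columns, clustered hierarchically with Ward's minimum
    variance method, cut into k clusters, and summarized by GO category per
    cluster. A seeded synthetic fixture generator provides complete,
    internally consistent input sets with planted condition-specific structure
    for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    jsonlite
Config/testthat/edition: 3
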