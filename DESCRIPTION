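Package: allokin
Title: Population Frequencies and Enzymatic Properties of ERAP1 Allotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying coding-SNP allotypes of the endoplasmic
    reticulum aminopeptidases ERAP1 and ERAP2: calling multi-site allotypes
    from phased genotype panels, estimating population allotype and diplotype
    frequencies and cross-gene co-occurrence, fitting Michaelis-Menten,
    allosteric (Hill) and four-parameter logistic models to enzymatic assay
    data, quantifying sequential peptide-trimming cascades, and combining
    allotype frequencies with catalytic efficiencies into genotype-activity
    landscapes. Includes seeded synthetic-data generators for every input so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    minpack.lm,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
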