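Package: littervar
Title: Genetic Control of Litter-Size Variability via LnVar and DHGLM
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the genetic control of litter-size variability
    in pig breeding populations. Implements two variability phenotypes for
    total number born (TNB): the log-transformed within-sow variance of
    residuals (LnVar) and the variance part of a double hierarchical
    generalized linear model (DHGLM), both fitted with a sparse pedigree
    animal-model REML/BLUP engine. Includes EBV deregression, theoretical
    accuracy, paternal half-sib cross-validation, a mixed-linear-model
    variance-QTL genome-wide association scan with genotype quality control,
    genomic relationship matrices and inflation-factor diagnostics, and a
    pedigree/genotype/phenotype simulator with planted variance QTL for
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
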