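Package: gdmdiag
Title: Integrative Methylation-Expression Analysis for Gestational
    Diabetes Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Workflow for discovering epigenetically driven diagnostic
    biomarkers of gestational diabetes mellitus (GDM) from paired placental
    DNA-methylation and gene-expression cohorts. Provides methylation
    preprocessing (beta to M-value conversion, missingness filtering,
    k-nearest-neighbour imputation, blacklist and promoter restriction),
    expression preprocessing, empirical-Bayes moderated-t differential
    expression, hypergeometric over-representation analysis of GMT gene
    sets, KGML pathway network parsing and merging, promoter
    methylation-expression negative-correlation screening with
    centrality-based hub-gene selection, and a linear support-vector-machine
    diagnostic classifier with cross-validation, external-cohort prediction
    and resampling stability. A synthetic-data generator emulating the
    paired-cohort study design makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    limma,
    stats,
    utils,
    xml2
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
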