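Package: pleiomod
Title: Disease-Module Detection and Pleiotropy Analysis on Gene Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects disease-associated network modules from per-gene
    differential-expression P-values by scoring maximal cliques of a
    protein-protein interaction network against gene-label permutation
    nulls, quantifies pleiotropic overlap of modules across diseases with
    randomized-null fold enrichment, computes degree-controlled enrichment
    statistics for gene annotations, and stratifies treatment responders
    with L1-penalized logistic classification under leave-one-out
    cross-validation. Includes a synthetic-data generator with planted
    modules so the full pipeline can be exercised end to end without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    glmnet,
    limma,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
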