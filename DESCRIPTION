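Package: platisig
Title: Mutational Signatures and Recurrently Mutated Genes in
    Cisplatin-Treated Exomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of somatic mutation tables from
    chemotherapy-exposed exomes: 96-trinucleotide mutation catalogs,
    de novo mutational-signature extraction by KL non-negative matrix
    factorization with bootstrap stability-based model selection,
    annotation against reference signatures and scoring of the platinum
    (C>A at CpCpR) signature, a significantly-mutated-gene test based on
    convolution of per-sample binomial background models, and Fisher
    exact enrichment between response groups and external cohorts. A
    synthetic-cohort generator with ground truth makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    BiocGenerics,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
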