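Package: btmsig
Title: Biterm Topic Models for Sparse Mutational Signature Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mutational signature analysis for sparse somatic mutation
    catalogs such as targeted sequencing panels. Models mutation
    co-occurrence within patients (biterms) with a biterm topic model
    fitted by expectation-maximization, selects the number of signatures
    by two-fold cross-validation with a Wilcoxon rank-sum rollback toward
    parsimony, and provides a companion mixture of multinomial mixture
    models that soft-clusters samples with per-cluster signature
    exposures, selected by BIC. Includes readers and writers for SBS-96
    count matrices and COSMIC-style signature tables, signature quality
    evaluation by cosine matching, and a synthetic catalog generator that
    emulates panel-level sparsity, heavy-tailed mutation burdens, and
    cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
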