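Package: ontosim
Title: Ontology-Based Inter-Patient Similarity with Literature-Derived
    Term Weighting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures similarity between clinical reports characterized by
    concepts from an is-a ontology. Extracted terms are projected onto a
    fixed level of feature concepts via edge-count semantic distances,
    turned into regularized feature vectors with weights estimated from
    literature co-occurrence counts (equal, generic, and report-specific
    schemes), and compared with the modified direction cosine. Pairwise
    similarity scores are evaluated as predictors of diagnosis
    co-occurrence with rank-based ROC analysis, Hanley-McNeil confidence
    intervals, and DeLong tests for correlated AUROCs. Includes seeded
    generators for synthetic ontologies, report cohorts, and abstract
    corpora with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
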