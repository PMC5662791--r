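Package: edurec
Title: Recommending Patient Education Materials for Consumer Health Questions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An information-retrieval toolkit for matching consumer health
    questions to expert-vetted patient education materials. Implements three
    query-document matching models: a TF-IDF vector space baseline, a topic
    modeling-based model built on collapsed Gibbs sampling for latent
    Dirichlet allocation with fold-in inference for unseen questions, and a
    semantic group-based model that treats coarse clinical semantic groups as
    topics via deterministic dictionary concept mapping. Includes corpus
    statistics, chi-square comparison of concept mapping rates, graded-relevance
    evaluation (precision at k with partial credit, weighted Cohen kappa),
    bipartite question-topic network construction with GraphML export, and
    synthetic corpus generators with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
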