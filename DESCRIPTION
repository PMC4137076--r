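Package: phenorepo
Title: Phenome-Guided Drug Repositioning with Latent Dirichlet Allocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring unobserved drug-indication links from a binary
    drug-by-phenome incidence matrix (side effects plus indications, in the
    style of SIDER). A latent Dirichlet allocation topic model fitted by
    collapsed Gibbs sampling yields per-drug phenotype probabilities
    p(ph|d) = sum_t p(t|d) p(ph|t); indication-restricted probabilities are
    renormalized per drug and accepted as repositioning candidates when they
    exceed the random-chance threshold q and rank within the drug's
    indication space (IS). Includes held-out perplexity model selection for
    the topic count, a leave-one-out masked-indication recovery harness with
    success-rate summaries, reverse drug-for-indication queries, and a
    seed-deterministic synthetic phenome generator with known latent
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
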