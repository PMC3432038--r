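Package: targetrank
Title: Network-Based Prioritization of Candidate Cancer Genes and Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ranks candidate cancer genes over a weighted gene functional
    network using hub scores (weighted degree or weighted eigenvector
    centrality on the tumor-specific subnetwork induced by the candidates)
    or a guilt-by-association seed-gene score (sum of direct linkage
    probabilities to a seed set). Maps drug-target catalogs onto the
    ranking to propose drug candidates, and validates rankings against
    benchmark gene sets with tie-corrected ROC/AUC, citation-cutoff sweeps
    and Spearman rank-citation correlation. Includes a synthetic network
    generator with planted hubs and planted benchmark truth for end-to-end
    testing, and a command-line interface with rank, drugs, evaluate and
    simulate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    Matrix,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
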