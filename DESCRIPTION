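Package: cdscore
Title: Local-Network-Topology Scoring of Transitive Chemical-Disease
    Inferences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks transitive chemical-disease inferences drawn from a
    tripartite chemical-gene-disease association network, such as the
    curated content of the Comparative Toxicogenomics Database (CTD).
    Implements five local-topology statistics on the -log10 scale: the
    hypergeometric mutual clustering coefficient, two common-neighbor
    statistics (one using the degrees of the inference endpoints, one
    using the degree of every connecting gene), and their unweighted and
    gene-count-weighted logarithmic opinion pools, together with
    Bonferroni correction, a degree-preserving edge-shuffle null model,
    ranking and tie diagnostics, a median-threshold classifier, and a
    seeded scale-free synthetic network generator with planted
    inferences so the whole pipeline is testable without a database
    download.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
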