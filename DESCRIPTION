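Package: cernet
Title: Competing Endogenous RNA Network Inference from Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA) networks
    from case/control expression profiles, as applied to polycystic ovary
    syndrome microarray data. Provides differential-expression screening by
    Welch t-test and signed fold change, miRNA target determination by seed
    matching (miRNA positions 2-8) with a simplified duplex free-energy filter,
    Pearson coexpression gating, competing-triplet assembly into a tripartite
    graph, degree-based hub and key-lncRNA analysis with subnetwork extraction,
    hypergeometric gene-set over-representation analysis, and a synthetic-data
    generator with planted ground truth so every stage can be validated without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    fgsea,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
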