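Package: imena
Title: Interdomain Molecular Ecological Network Analysis for Multi-Kingdom Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds and analyses interdomain molecular ecological networks (MENs)
    from multi-kingdom OTU tables (prokaryotes, fungi, cercozoa). Covers
    rarefaction, prevalence filtering, alpha diversity and guild annotation;
    Spearman co-occurrence networks with random-matrix-theory (RMT) threshold
    selection via the nearest-neighbour spacing distribution of unfolded
    eigenvalues; network topology, vulnerability and robustness under node
    removal; fast-greedy module detection with Zi/Pi keystone classification;
    SVD module eigengenes correlated with environmental traits and methane flux;
    and community-level statistics (Jaccard distances, Mantel tests, PCA,
    MRPP/ANOSIM/PERMANOVA). A seeded synthetic multi-kingdom community
    generator with planted correlation modules and a flux-linked module
    eigengene makes every stage testable without sequencing data.
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
    igraph,
    jsonlite,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
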