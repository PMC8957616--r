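Package: mnpnet
Title: Microbiome Co-Occurrence Networks of Populations and Individuals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Compositional preprocessing, sparse co-occurrence network
    inference and network comparison for species-collapsed 16S count
    tables. Implements taxon filtering, rarefaction and the centered
    log-ratio transform; Meinshausen-Buhlmann neighbourhood selection
    with StARS stability-based regularization selection; population
    networks (MNP), leave-one-out single-sample networks (MNI) and
    bootstrap network ensembles; targeted-attack fragility curves,
    natural connectivity and AUC robustness scores; bootstrap and
    paired Wilcoxon comparison of network and lipid summary metrics;
    and a logistic-normal-multinomial generator of synthetic count
    tables with known association networks for method validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    MASS,
    stats,
    tools,
    utils,
    vegan
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
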