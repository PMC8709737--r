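Package: DiffNetBackbone
Title: Disparity-Filtered Differential Correlation Networks for
    Two-Group Metabolomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers a permutation-validated differential Pearson
    correlation network between two phenotype groups of a metabolite
    abundance table, reduces it to its multiscale backbone with the
    disparity filter, characterises hub and bottleneck metabolites by
    degree and betweenness centrality, and trains and evaluates a
    PLS-DA classifier on network-derived features (connected backbone
    nodes plus one interaction term per backbone edge). Includes a
    synthetic two-group generator with planted differential
    correlations so the whole workflow is testable without external
    data, and an end-to-end pipeline driver with fixed-seed
    reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AbundanceTable-class.R'
    'DiffNetBackbone-package.R'
    'DifferentialNetwork-class.R'
    'data-io.R'
    'differential-network.R'
    'disparity-filter.R'
    'feature-engineering.R'
    'network-topology.R'
    'pipeline.R'
    'plsda.R'
    'synthetic-data.R'
    'utils.R'
biocViews: Metabolomics, Network, Classification, GraphAndNetwork
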