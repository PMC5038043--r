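Package: plaquenet
Title: Diversity, Differential Abundance, and Cooccurrence Networks for
    Supragingival Plaque Communities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for separating gingivitis-associated from
    periodontitis-associated signals in supragingival-plaque taxon count
    data. Provides rarefaction-based alpha diversity with backward
    stepwise covariate modeling, negative-binomial GLM differential
    abundance with median-of-ratios normalization and Benjamini-Hochberg
    correction, SparCC compositional correlation inference with
    permutation significance, strong-edge cooccurrence networks with
    betweenness centrality, Mantel-distance clustering of per-stratum
    correlation matrices, Bray-Curtis/PCoA ordination, percent-identity
    phylotype selection, and a calibrated synthetic-cohort generator so
    the whole pipeline can be exercised and validated without external
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    igraph,
    ape,
    Biostrings,
    biomformat,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
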