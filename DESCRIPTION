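Package: conetwork
Title: Weighted Gene Co-Expression Network Analysis for Leukocyte Transcriptomes
Version: 1.0.0
Authors@R: person("conetwork", "developers", role = c("aut", "cre"),
    email = "conetwork@example.org")
Description: End-to-end weighted gene co-expression network analysis:
    covariate residualization, signed/unsigned soft-threshold adjacency,
    topological overlap, hierarchical module detection with a hybrid
    dynamic tree cut, module eigengenes and membership statistics,
    eigengene merging, hub calling, module annotation by marker-list
    hypergeometric enrichment and eigengene-trait correlation,
    cross-network module overlap, guilt-by-association function
    prediction for long non-coding RNAs, and query tools over a
    completed network run. Includes a seeded synthetic-data generator
    that plants latent-factor module structure, anti-correlated genes,
    trait loadings and covariate effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
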