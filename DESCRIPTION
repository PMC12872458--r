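Package: epocflow
Title: Sister-Clade Inference for Eukaryotic Gene Families by
    Constrained-Topology Likelihood Testing
Version: 0.1.0
Authors@R:
    person("Vale", "Odum", email = "vodum@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for inferring the prokaryotic sister
    clade of eukaryotic gene families. Provides gene-tree curation
    (log-normal long-branch pruning, weighted midpoint rooting),
    taxonomy-aware clade detection with a soft-LCA purity/scope score,
    amino-acid likelihood computation under empirical models with
    discrete gamma rates, constrained-topology hypothesis testing via
    expected likelihood weights (RELL), FECA-to-LECA stem-length
    statistics, soft-core pangenome and core-set filtering with aELW
    aggregation by functional category, and greedy set-cover cluster
    annealing with distance-embedding tree partitioning. A seeded
    synthetic gene-family generator with known ground truth makes every
    stage testable without external sequence databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
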