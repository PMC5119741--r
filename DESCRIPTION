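Package: phmmindex
Title: Cluster-Based Acceleration of Profile-HMM Database Retrieval
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Accelerates homology search against databases of profile hidden
    Markov models by remodeling the database as clusters. Builds a
    max-symmetrized all-against-all similarity matrix on the 0-100
    profile-profile probability scale, clusters it with single-linkage
    agglomeration, k-means, or connected components, selects a medoid-like
    representative per cluster by maximum within-cluster similarity sum, and
    optionally re-assigns profiles to overlapping clusters under a
    self-regulated per-profile threshold. Queries are answered by a staged
    representatives-first search with exact comparison-count accounting, and
    recall and comparison-cost reduction are evaluated against exhaustive
    sequential search. Includes seeded planted-partition generators so the
    whole pipeline is testable without external alignment tools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
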