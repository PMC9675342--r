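Package: playseq
Title: Sequence Structure, Predictability and Games in Animal Social Play
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing coded sequences of discrete behavioural
    elements from animal social play. Provides pre-processing of event logs
    (lumping of rare elements, collapse of continuous-state repeats, random
    linearization of co-occurring elements), fractional transition counting
    with a bout-preserving permutation null model, bootstrap robustness
    intervals, next-element prediction with interpolated Laplace-smoothed
    n-gram models and a naive Bayes comparison under k-fold validation,
    clustering of elements by transition-profile similarity (UMAP embedding,
    silhouette-selected k-means, hierarchical dendrograms, consensus over
    repeated runs), and community detection on significance-filtered
    transition networks, including within- versus between-community
    transition statistics. A synthetic-sequence generator with planted
    "game" structure supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    mclust,
    igraph,
    uwot,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
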