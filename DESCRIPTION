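Package: dreamnet
Title: Rank-Based Classification and Co-Occurrence Networks of Health
    Mentions in Two Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares mentions of medical conditions between two text
    corpora (e.g. waking-life social media discussions and dream reports)
    using frequency ranks rather than raw counts.  Conditions are
    partitioned into classes (typical of one corpus, equally prevalent,
    typical of the other) by an iterative linear-regression residual
    procedure on rank pairs, and a comorbidity-style co-occurrence network
    of conditions is built from per-report condition sets, with relative
    risk and phi-coefficient edge statistics, significance filtering,
    PageRank centrality, attribute assortativity and component analysis.
    Includes a synthetic corpus generator with planted prevalence classes
    and co-occurrence clusters for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
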