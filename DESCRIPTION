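Package: semdrift
Title: Multi-Model Diachronic Word Embeddings for Semantic Change Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects changes in word usage across year-binned text corpora,
    with an emphasis on biomedical literature carrying entity annotations.
    Trains replicate CBOW word-embedding models per year with a seeded
    single-threaded trainer, aligns every model to an anchor model by
    orthogonal Procrustes, builds per-token change time series from an
    integrated inter-/intra-year cosine-distance ratio combined with a
    token-frequency ratio, and calls changepoints with a CUSUM procedure
    thresholded at a global percentile of all generated timepoints. Includes
    a synthetic-corpus generator with planted context shifts and frequency
    changes so the whole pipeline can be validated end to end, plus
    nearest-neighbour reporting through time.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
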