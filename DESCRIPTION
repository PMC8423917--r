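Package: switchnet
Title: Semantic Network Analysis of Bilingual Code-Switching Speech
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying bilingual code-switching (CS) speech with
    network science. Reads language-tagged bilingual corpora, classifies
    sentences into non-CS, intra-sentential, and inter-sentential CS types,
    trains skip-gram word embeddings, builds weighted semantic networks with
    cosine-similarity edges, detects language communities by modularity
    optimisation, and compares the weighted clustering coefficients and
    frequencies of code-switched words against their translation equivalents
    with a battery of paired, mixed-design, and nonparametric tests. Includes
    a synthetic bilingual-corpus generator with planted switching effects so
    the full pipeline can be exercised and validated without access to
    licensed speech corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
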