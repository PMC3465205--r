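Package: themeclust
Title: Thematic Clustering of Text Documents by EM Subject-Term Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Hard clustering of text documents in a Bernoulli
    term-occurrence model, where each cluster (theme) is characterized
    jointly by a set of subject terms and the documents in which those
    terms occur with elevated probability.  An EM procedure alternates
    per-cluster estimation of in-theme and out-of-theme term occurrence
    probabilities, selection of the highest-gain subject terms, posterior
    document membership, and hard reassignment; empty clusters are pruned
    so the final cluster count is data-driven.  Includes model selection
    across random restarts by a theme score, clustering evaluation
    (normalized mutual information, paired F-score over subject-term
    sets, cluster title selection, hypergeometric label enrichment),
    corpus readers with unigram/bigram term extraction, a planted-theme
    synthetic corpus generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
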