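# The planted three-theme study corpus used by the recovery and
# model-selection tests: 3 themes x 100 documents, 30 theme terms per theme,
# 500 background terms, p_in = 0.3, p_out = 0.01, p_background = 0.05
# (the generator defaults).  Built once per test run and cached.
study_corpus_cache <- new.env(parent = emptyenv())

study_corpus <- function() {
  if (is.null(study_corpus_cache$corp)) {
    corp <- planted_corpus(seed = 101)
    inc <- build_incidence(corp$documents, stopwords = character(),
                           min_doc_freq = 2, bigrams = FALSE)
    study_corpus_cache$corp <- corp
    study_corpus_cache$inc <- inc
  }
  list(corp = study_corpus_cache$corp, inc = study_corpus_cache$inc)
}

# Fraction of theme j's planted terms found among cluster i's subject terms,
# for the cluster that best matches each theme.
planted_term_recovery <- function(fit, corp) {
  vapply(seq_along(corp$theme_terms), function(j) {
    max(vapply(fit$clusters, function(cl)
      mean(corp$theme_terms[[j]] %in% cl$terms), numeric(1)))
  }, numeric(1))
}
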