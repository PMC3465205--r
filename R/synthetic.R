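#' Generate a planted-theme corpus
#'
#' Draws a corpus from the same independent-Bernoulli occurrence model the
#' clustering assumes: each document belongs to exactly one latent theme;
#' it contains each of its own theme's terms with probability `p_in`, each
#' other theme's terms with probability `p_out`, and each background term
#' with probability `p_background`.  Terms are emitted as single
#' alphanumeric tokens (e.g. `"t2w007"`, `"bgw013"`) so tokenization is
#' exercised without creating unintended bigrams; with
#' `bigram_terms = TRUE` each theme term is a two-token phrase
#' (`"t2w007a t2w007b"`) to exercise bigram extraction.  Token order within
#' a document is shuffled (at the term level, so multi-token terms stay
#' adjacent).  Fully deterministic under `seed`.
#'
#' The defaults describe a moderately hard recovery problem: theme terms
#' three times denser inside their theme than the background rate, plus a
#' large uninformative background vocabulary.
#'
#' @param n_themes Number of latent themes.
#' @param docs_per_theme Documents generated per theme.
#' @param theme_vocab_size Terms private to each theme.
#' @param background_vocab_size Background terms shared by all documents.
#' @param p_in Occurrence probability of a theme term in its own theme.
#' @param p_out Occurrence probability of a theme term elsewhere
#'   (must be < `p_in`).
#' @param p_background Occurrence probability of a background term anywhere.
#' @param seed Integer seed (drawn from the session RNG when `NULL`).
#' @param bigram_terms Emit theme terms as two-token phrases?
#' @return List with `documents` (data.frame `doc_id`, `text`), `labels`
#'   (named integer theme per document), `theme_terms` (list of term sets,
#'   pairwise disjoint), and `spec` (the generating parameters).
#' @export
#' @examples
#' corp <- planted_corpus(n_themes = 2, docs_per_theme = 5,
#'                        theme_vocab_size = 4, background_vocab_size = 10,
#'                        p_in = 0.9, p_out = 0, seed = 1)
#' corp$documents$text[1]
planted_corpus <- function(n_themes = 3L, docs_per_theme = 100L,
                           theme_vocab_size = 30L,
                           background_vocab_size = 500L,
                           p_in = 0.3, p_out = 0.01, p_background = 0.05,
                           seed = NULL, bigram_terms = FALSE) {
  stopifnot(n_themes >= 1L, docs_per_theme >= 1L, theme_vocab_size >= 1L,
            background_vocab_size >= 1L,
            p_out >= 0, p_out < p_in, p_in <= 1,
            p_background >= 0, p_background <= 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1L)

  term_name <- function(theme, j) {
    base <- sprintf("t%dw%03d", theme, j)
    if (bigram_terms) paste0(base, "a ", base, "b") else base
  }
  theme_terms <- lapply(seq_len(n_themes), function(i)
    vapply(seq_len(theme_vocab_size), function(j) term_name(i, j),
           character(1)))
  bg_terms <- sprintf("bgw%03d", seq_len(background_vocab_size))
  all_terms <- c(unlist(theme_terms), bg_terms)
  term_theme <- c(rep(seq_len(n_themes), each = theme_vocab_size),
                  rep(0L, background_vocab_size))

  n_docs <- n_themes * docs_per_theme
  labels <- rep(seq_len(n_themes), each = docs_per_theme)
  doc_ids <- sprintf("doc%04d", seq_len(n_docs))

  texts <- with_seed(seed, vapply(seq_len(n_docs), function(d) {
    probs <- ifelse(term_theme == 0L, p_background,
                    ifelse(term_theme == labels[d], p_in, p_out))
    present <- all_terms[stats::runif(length(all_terms)) < probs]
    if (length(present) == 0L) return("")
    if (length(present) > 1L) present <- sample(present)
    paste(unlist(strsplit(present, " ", fixed = TRUE)), collapse = " ")
  }, character(1)))

  list(documents = data.frame(doc_id = doc_ids, text = texts,
                              stringsAsFactors = FALSE),
       labels = stats::setNames(labels, doc_ids),
       theme_terms = theme_terms,
       spec = list(n_themes = n_themes, docs_per_theme = docs_per_theme,
                   theme_vocab_size = theme_vocab_size,
                   background_vocab_size = background_vocab_size,
                   p_in = p_in, p_out = p_out, p_background = p_background,
                   seed = seed, bigram_terms = bigram_terms))
}

#' Analytic term statistics of a planted corpus
#'
#' Closed-form expectations, under the generating model and the true
#' labels, of the quantities the estimator computes: for a theme term,
#' E\[p_t\] = `p_in`, E\[q_t\] = `p_out` and the background rate is the
#' label-weighted mixture
#' \eqn{E[r_t] = (p_{in} + (K-1)\,p_{out})/K}; for a background term all
#' three equal `p_background`.  Used to assert parameter recovery against
#' sampling noise.
#'
#' @inheritParams planted_corpus
#' @return data.frame with one row per term class (`theme`, `background`)
#'   and columns `E_p`, `E_q`, `E_r`, `E_n_t`.
#' @export
#' @examples
#' expected_term_stats(n_themes = 3, docs_per_theme = 100,
#'                     p_in = 0.3, p_out = 0.01, p_background = 0.05)
expected_term_stats <- function(n_themes = 3L, docs_per_theme = 100L,
                                p_in = 0.3, p_out = 0.01,
                                p_background = 0.05) {
  stopifnot(n_themes >= 1L, docs_per_theme >= 1L,
            p_out >= 0, p_out < p_in, p_in <= 1,
            p_background >= 0, p_background <= 1)
  r_theme <- (p_in + (n_themes - 1) * p_out) / n_themes
  data.frame(
    class = c("theme", "background"),
    E_p = c(p_in, p_background),
    E_q = c(p_out, p_background),
    E_r = c(r_theme, p_background),
    E_n_t = c(docs_per_theme * (p_in + (n_themes - 1) * p_out),
              n_themes * docs_per_theme * p_background))
}
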