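#' Normalized mutual information between two partitions
#'
#' \deqn{NMI = \frac{\sum_{h,l} m_{h,l} \log\frac{m\, m_{h,l}}{m_h c_l}}
#'   {\sqrt{\sum_h m_h \log\frac{m_h}{m} \sum_l c_l \log\frac{c_l}{m}}}}
#' where m is the number of documents, m_h and c_l the cluster sizes of the
#' two partitions and m_(h,l) the joint counts.  Natural logarithms (the
#' base cancels).  NMI is 1 for identical partitions, 0 for independent
#' ones; it is symmetric and invariant to cluster relabelling.  When either
#' partition has a single cluster the formula is 0/0; the convention used is
#' 1 if the partitions are identical and 0 otherwise.
#'
#' @param predicted,truth Cluster label vectors over the same documents.
#'   When both are named they are aligned by name (an error if the document
#'   sets differ); otherwise they are matched positionally.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' nmi(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' nmi(c(1, 1, 2, 2), c(1, 2, 1, 2))          # 0
nmi <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth)))
      stop("predicted and truth cover different document sets")
    truth <- truth[names(predicted)]
  } else if (length(predicted) != length(truth)) {
    stop("predicted and truth have different lengths and no names to align")
  }
  m <- length(predicted)
  stopifnot(m >= 1L)
  tab <- table(factor(predicted), factor(truth))
  if (nrow(tab) == 1L || ncol(tab) == 1L)
    return(as.numeric(nrow(tab) == 1L && ncol(tab) == 1L))
  mh <- rowSums(tab)
  cl <- colSums(tab)
  joint <- as.vector(tab)
  expct <- as.vector(outer(mh, cl))
  nz <- joint > 0
  num <- sum(joint[nz] * log(m * joint[nz] / expct[nz]))
  den <- sqrt(sum(mh * log(mh / m)) * sum(cl * log(cl / m)))
  num / den
}

pair_set <- function(term_sets) {
  pairs <- lapply(term_sets, function(ts) {
    ts <- sort(unique(ts))
    if (length(ts) < 2L) return(character())
    cmb <- utils::combn(ts, 2L)
    paste(cmb[1L, ], cmb[2L, ], sep = "\r")
  })
  unique(unlist(pairs, use.names = FALSE))
}

#' Paired F-score between two subject-term clusterings
#'
#' Each side's clusters are expanded into the set of unordered within-cluster
#' term pairs; precision and recall are the shared-pair fractions of each
#' side and F is their harmonic mean.  Used to compare the subject-term
#' output of two runs (a stability measure): 1 means identical per-cluster
#' term sets, 0 means no shared pair.
#'
#' @param terms_a,terms_b Lists of character vectors, one per cluster.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' paired_fscore(list(c("a", "b", "c")), list(c("a", "b", "d")))  # 1/3
paired_fscore <- function(terms_a, terms_b) {
  a <- pair_set(terms_a)
  b <- pair_set(terms_b)
  if (length(a) == 0L || length(b) == 0L)
    stop("a side has no cluster with at least two terms: no pairs to compare")
  common <- length(intersect(a, b))
  if (common == 0L) return(0)
  prec <- common / length(a)
  rec <- common / length(b)
  2 * prec * rec / (prec + rec)
}

# Does term (a unigram or space-joined n-gram) occur in a token sequence,
# n-grams requiring consecutive tokens?
term_in_tokens <- function(term, tokens) {
  parts <- strsplit(term, " ", fixed = TRUE)[[1L]]
  np <- length(parts)
  if (np == 1L) return(term %in% tokens)
  nt <- length(tokens)
  if (nt < np) return(FALSE)
  for (s in seq_len(nt - np + 1L))
    if (all(tokens[s:(s + np - 1L)] == parts)) return(TRUE)
  FALSE
}

#' Title score of a candidate phrase
#'
#' \eqn{T(P) = \sum_{t \subseteq P} \alpha_t \cdot DF(t)} — the sum, over
#' the subject terms contained in the phrase (unigrams by token membership,
#' bigrams and longer by consecutive containment), of the term's alpha gain
#' times its document frequency.
#'
#' @param phrase Character vector of tokens (or a single space-separated
#'   string).
#' @param alpha Named numeric vector of subject-term gains.
#' @param doc_freq Named numeric vector of document frequencies DF(t) for
#'   the same terms.
#' @return The score T(P).
#' @export
title_score <- function(phrase, alpha, doc_freq) {
  if (length(phrase) == 1L && grepl(" ", phrase, fixed = TRUE))
    phrase <- strsplit(phrase, " ", fixed = TRUE)[[1L]]
  stopifnot(length(phrase) >= 1L, !is.null(names(alpha)))
  terms <- names(alpha)
  hit <- vapply(terms, term_in_tokens, logical(1), tokens = phrase)
  if (!any(hit)) return(0)
  sum(alpha[hit] * doc_freq[names(alpha)[hit]])
}

#' Select a title phrase for a cluster
#'
#' Candidate phrases are all contiguous token windows of length 1 to
#' `max_len` occurring in the cluster's documents; the candidate with the
#' highest title score [title_score()] is returned (ties: shorter phrase,
#' then lexicographic).  DF(t) is counted within the cluster's documents.
#' Candidate generation from token windows is a deliberately simple stand-in
#' for noun-phrase chunking and suffices for run-to-run stability
#' comparison.
#'
#' @param docs List of token vectors (one per cluster document), or a
#'   character vector of raw texts which are tokenized with `stopwords`.
#' @param alpha Named numeric vector of subject-term gains for the cluster.
#' @param max_len Maximum candidate phrase length in tokens.
#' @param stopwords Stopword list used only when `docs` are raw texts.
#' @return List with `phrase` (string), `score`, and `supporting_terms`
#'   (data.frame of the contained subject terms with their alpha and DF).
#' @export
select_title <- function(docs, alpha, max_len = 4L,
                         stopwords = default_stopwords()) {
  if (is.character(docs)) docs <- lapply(docs, tokenize, stopwords = stopwords)
  stopifnot(is.list(docs), length(docs) >= 1L, !is.null(names(alpha)))
  terms <- names(alpha)
  doc_freq <- stats::setNames(vapply(terms, function(t)
    sum(vapply(docs, function(tk) term_in_tokens(t, tk), logical(1))),
    numeric(1)), terms)

  windows <- function(tk) {
    n <- length(tk)
    if (n == 0L) return(character())
    unlist(lapply(seq_len(min(max_len, n)), function(L)
      vapply(seq_len(n - L + 1L), function(s)
        paste(tk[s:(s + L - 1L)], collapse = " "), character(1))))
  }
  cand <- unique(unlist(lapply(docs, windows), use.names = FALSE))
  if (length(cand) == 0L)
    stop("no candidate phrases: cluster documents are empty")

  scores <- vapply(cand, title_score, numeric(1),
                   alpha = alpha, doc_freq = doc_freq)
  n_tok <- lengths(strsplit(cand, " ", fixed = TRUE))
  best <- order(-scores, n_tok, cand)[1L]
  contained <- vapply(terms, term_in_tokens, logical(1),
                      tokens = strsplit(cand[best], " ", fixed = TRUE)[[1L]])
  list(phrase = cand[best],
       score = unname(scores[best]),
       supporting_terms = data.frame(
         term = terms[contained],
         alpha = unname(alpha[contained]),
         doc_freq = unname(doc_freq[contained]),
         row.names = NULL))
}

#' Hypergeometric label enrichment of a cluster
#'
#' For each document label (e.g. a controlled-vocabulary annotation such as
#' a MeSH heading) occurring in the cluster, the upper-tail hypergeometric
#' probability of drawing at least the observed number of labelled documents
#' when `cluster size` documents are sampled from the corpus.  Small
#' p-values indicate the cluster is enriched for the label, i.e. not a
#' random grouping.  Raw p-values, no multiplicity correction.
#'
#' @param cluster_doc_ids Character vector of the cluster's document ids
#'   (must be a subset of `corpus_doc_ids`).
#' @param doc_labels data.frame with columns `doc_id`, `label` (a document
#'   may appear on several rows, one per label).
#' @param corpus_doc_ids Character vector of all corpus document ids.
#' @return data.frame with columns `label`, `p_value`, `cluster_count`,
#'   `cluster_size`, `corpus_count`, `corpus_size`, sorted by ascending
#'   p-value (ties: label).
#' @export
label_enrichment <- function(cluster_doc_ids, doc_labels, corpus_doc_ids) {
  stopifnot(is.data.frame(doc_labels),
            all(c("doc_id", "label") %in% names(doc_labels)))
  if (!all(cluster_doc_ids %in% corpus_doc_ids))
    stop("cluster document ids are not a subset of the corpus")
  doc_labels <- unique(doc_labels[doc_labels$doc_id %in% corpus_doc_ids,
                                  c("doc_id", "label")])
  n_corpus <- length(unique(corpus_doc_ids))
  cluster_doc_ids <- unique(cluster_doc_ids)
  n_cluster <- length(cluster_doc_ids)

  in_cluster <- doc_labels$doc_id %in% cluster_doc_ids
  labels <- sort(unique(doc_labels$label[in_cluster]))
  if (length(labels) == 0L)
    return(data.frame(label = character(), p_value = numeric(),
                      cluster_count = integer(), cluster_size = integer(),
                      corpus_count = integer(), corpus_size = integer()))
  res <- do.call(rbind, lapply(labels, function(lab) {
    rows <- doc_labels$label == lab
    k_corpus <- sum(rows)
    k_clust <- sum(rows & in_cluster)
    p <- stats::phyper(k_clust - 1L, k_corpus, n_corpus - k_corpus,
                       n_cluster, lower.tail = FALSE)
    data.frame(label = lab, p_value = p,
               cluster_count = k_clust, cluster_size = n_cluster,
               corpus_count = k_corpus, corpus_size = n_corpus)
  }))
  res <- res[order(res$p_value, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}
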