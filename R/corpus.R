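#' Default English stopword list
#'
#' Returns the stopword list shipped with the package (one word per line in
#' `inst/extdata/stopwords_en.txt`).  The list is a conventional set of
#' English function words; it is a default, not a fixed part of the model —
#' every function that filters stopwords accepts an arbitrary character
#' vector instead.
#'
#' @return Character vector of lowercase stopwords.
#' @export
#' @examples
#' head(default_stopwords())
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "themeclust")
  readLines(path, warn = FALSE)
}

#' Tokenize text
#'
#' Lowercases, splits on runs of non-alphanumeric characters, drops empty
#' strings and stopwords.  Token order is preserved, so adjacent surviving
#' tokens can later form bigram terms.
#'
#' @param text A character scalar (or vector, concatenated with spaces).
#' @param stopwords Character vector of words to drop after lowercasing.
#' @return Character vector of tokens (possibly empty).
#' @export
#' @examples
#' tokenize("Deep Brain stimulation.", stopwords = character())
#' tokenize("the lewy bodies", stopwords = "the")
tokenize <- function(text, stopwords = default_stopwords()) {
  if (length(text) == 0L) return(character())
  text <- paste(text, collapse = " ")
  toks <- strsplit(tolower(text), "[^a-z0-9]+")[[1L]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% stopwords]
}

#' Extract unigram and bigram terms from a token stream
#'
#' Terms are the distinct unigrams plus, when `bigrams = TRUE`, the distinct
#' bigrams formed from adjacent tokens of the (already stopword-filtered)
#' stream, each bigram rendered as the two tokens joined by a single space.
#' Returned sorted, as a set.
#'
#' @param tokens Character vector of tokens, already stopword-filtered.
#' @param bigrams Include adjacent-token bigrams?
#' @return Sorted character vector of distinct terms.
#' @export
#' @examples
#' extract_terms(c("deep", "brain", "stimulation"))
extract_terms <- function(tokens, bigrams = TRUE) {
  if (length(tokens) == 0L) return(character())
  terms <- tokens
  if (bigrams && length(tokens) >= 2L) {
    n <- length(tokens)
    terms <- c(terms, paste(tokens[-n], tokens[-1L]))
  }
  sort(unique(terms))
}

#' Build the binary term-document incidence relation
#'
#' Tokenizes each document, extracts unigram (and optionally bigram) terms,
#' and assembles the binary incidence matrix \eqn{\delta_{td}} (1 when term
#' t occurs in document d).  The vocabulary is the union of extracted terms
#' restricted to those occurring in at least `min_doc_freq` documents, in
#' lexicographic order; documents keep input order.  Occurrence is
#' presence-only (Bernoulli semantics), never a count.
#'
#' @param docs A data.frame with character columns `doc_id` and `text`
#'   (`doc_id` unique), or a named character vector of texts.
#' @param stopwords Stopword list passed to [tokenize()].
#' @param min_doc_freq Minimum number of documents a term must occur in.
#' @param bigrams Include adjacent-token bigram terms?
#' @return An object of class `"incidence"`: a list with `incidence` (sparse
#'   binary term-by-document `Matrix::dgCMatrix`), `terms`, `doc_ids`,
#'   `term_doc_freq` (n_t per term) and `n_docs` (N).
#' @export
#' @examples
#' docs <- data.frame(doc_id = c("d1", "d2"), text = c("a b", "b c"))
#' inc <- build_incidence(docs, stopwords = character(), min_doc_freq = 1)
#' inc$term_doc_freq
build_incidence <- function(docs, stopwords = default_stopwords(),
                            min_doc_freq = 2L, bigrams = TRUE) {
  if (is.character(docs)) {
    ids <- names(docs)
    if (is.null(ids)) ids <- as.character(seq_along(docs))
    docs <- data.frame(doc_id = ids, text = unname(docs),
                       stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(docs), all(c("doc_id", "text") %in% names(docs)),
            nrow(docs) >= 1L, min_doc_freq >= 1L)
  if (anyDuplicated(docs$doc_id))
    stop("duplicate doc_id values in corpus")

  term_sets <- lapply(docs$text, function(txt)
    extract_terms(tokenize(txt, stopwords), bigrams = bigrams))

  all_terms <- unlist(term_sets, use.names = FALSE)
  if (length(all_terms) == 0L)
    stop("empty vocabulary: no terms survive preprocessing")
  df_tab <- table(all_terms)  # each doc contributes a term at most once
  keep <- sort(names(df_tab)[df_tab >= min_doc_freq])
  if (length(keep) == 0L)
    stop("empty vocabulary: no term reaches min_doc_freq = ", min_doc_freq)

  idx <- lapply(term_sets, function(ts) {
    m <- match(ts, keep)
    m[!is.na(m)]
  })
  j <- rep.int(seq_along(idx), lengths(idx))
  i <- unlist(idx, use.names = FALSE)
  X <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(keep), nrow(docs)),
                            dimnames = list(keep, docs$doc_id))
  X <- methods::as(X, "CsparseMatrix")
  structure(list(incidence = X,
                 terms = keep,
                 doc_ids = docs$doc_id,
                 term_doc_freq = stats::setNames(Matrix::rowSums(X), keep),
                 n_docs = nrow(docs)),
            class = "incidence")
}

#' @export
print.incidence <- function(x, ...) {
  cat("Term-document incidence relation\n")
  cat(sprintf("  %d terms x %d documents, %d nonzero entries\n",
              length(x$terms), x$n_docs, length(x$incidence@x)))
  cat(sprintf("  median document frequency n_t: %g\n",
              stats::median(x$term_doc_freq)))
  invisible(x)
}

#' Read a corpus of documents
#'
#' Supported formats: `"dir"` — a directory of plain-text files, one document
#' per file, `doc_id` = file name; `"jsonl"` — JSON Lines, one object per
#' line with fields `id` and `text`; `"tsv"` — tab-separated with three
#' columns `id`, `title`, `abstract` (no header; title and abstract are
#' concatenated with a space).
#'
#' @param path Directory (for `"dir"`) or file path.
#' @param format One of `"dir"`, `"jsonl"`, `"tsv"`.
#' @return data.frame with columns `doc_id`, `text`.
#' @export
read_corpus <- function(path, format = c("dir", "jsonl", "tsv")) {
  format <- match.arg(format)
  switch(format,
    dir = {
      files <- list.files(path, full.names = TRUE)
      files <- files[!dir.exists(files)]
      if (length(files) == 0L) stop("no files in directory: ", path)
      data.frame(
        doc_id = basename(files),
        text = vapply(files, function(f)
          paste(readLines(f, warn = FALSE), collapse = " "), character(1)),
        stringsAsFactors = FALSE)
    },
    jsonl = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0L) stop("empty JSON Lines file: ", path)
      recs <- lapply(lines, jsonlite::fromJSON)
      bad <- !vapply(recs, function(r)
        all(c("id", "text") %in% names(r)), logical(1))
      if (any(bad))
        stop("JSON Lines record missing 'id' or 'text' at line ",
             which(bad)[1L])
      data.frame(
        doc_id = vapply(recs, function(r) as.character(r$id), character(1)),
        text = vapply(recs, function(r) as.character(r$text), character(1)),
        stringsAsFactors = FALSE)
    },
    tsv = {
      tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                               quote = "", colClasses = "character")
      if (ncol(tab) < 3L)
        stop("tsv corpus needs three columns: id, title, abstract")
      data.frame(doc_id = tab[[1L]],
                 text = paste(tab[[2L]], tab[[3L]]),
                 stringsAsFactors = FALSE)
    })
}

#' Write / read an incidence relation as Matrix Market plus sidecars
#'
#' `write_incidence()` writes `<prefix>.mtx` (coordinate format, 1-based
#' indices), `<prefix>.terms.txt` and `<prefix>.docs.txt` (one entry per
#' line).  `read_incidence()` reverses it exactly.
#'
#' @param x An `"incidence"` object.
#' @param prefix Path prefix for the three files.
#' @return `write_incidence`: `prefix`, invisibly. `read_incidence`: an
#'   `"incidence"` object.
#' @export
write_incidence <- function(x, prefix) {
  stopifnot(inherits(x, "incidence"))
  Matrix::writeMM(x$incidence, paste0(prefix, ".mtx"))
  writeLines(x$terms, paste0(prefix, ".terms.txt"))
  writeLines(x$doc_ids, paste0(prefix, ".docs.txt"))
  invisible(prefix)
}

#' @rdname write_incidence
#' @export
read_incidence <- function(prefix) {
  # readMM yields a pattern matrix for all-ones files; back to numeric 0/1
  X <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix") * 1
  terms <- readLines(paste0(prefix, ".terms.txt"))
  doc_ids <- readLines(paste0(prefix, ".docs.txt"))
  stopifnot(nrow(X) == length(terms), ncol(X) == length(doc_ids))
  dimnames(X) <- list(terms, doc_ids)
  structure(list(incidence = X, terms = terms, doc_ids = doc_ids,
                 term_doc_freq = stats::setNames(Matrix::rowSums(X), terms),
                 n_docs = length(doc_ids)),
            class = "incidence")
}
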