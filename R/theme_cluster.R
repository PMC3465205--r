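# Evaluate expr with a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# One EM sweep's cluster model from a membership weight vector (soft
# posteriors, or binary indicators for the initial partition and the final
# refit).  A weight vector with no outside mass has no evidence for q; it
# falls back to the background rate r, keeping alpha finite.
fit_cluster_model <- function(X, w, n_u, r, n_t, N) {
  if (sum(w) >= N) {
    n_st <- as.vector(X %*% w)
    pars <- list(p = clamp_prob(n_st / sum(w)), q = r, n_s = sum(w),
                 n_st = stats::setNames(n_st, rownames(X)))
  } else {
    pars <- estimate_cluster_params(X, w)
  }
  alpha <- compute_alpha(pars$p, pars$q, r, pars$n_s, pars$n_st, n_t, N)
  names(alpha) <- rownames(X)
  subject <- select_subject_terms(alpha, n_u)
  c(pars, list(alpha = alpha, subject = subject))
}

# The classification-EM loop.  Each sweep estimates every cluster's
# parameters from the current hard partition (Bernoulli occurrence
# frequencies inside and outside the cluster), selects its subject terms,
# scores every document's posterior membership, and reassigns each document
# to its argmax cluster; clusters that win no document are pruned, which is
# how the effective K shrinks.  Convergence is exact equality of
# consecutive argmax assignments, tested before the weakest-member
# mutation.
theme_em_once <- function(inc, k, n_u, prior, seed, max_iter, reassign_frac,
                          verbose = FALSE) {
  X <- inc$incidence
  N <- inc$n_docs
  n_t <- as.vector(inc$term_doc_freq)
  r <- estimate_background(inc)

  assignment <- with_seed(seed, sample.int(k, N, replace = TRUE))
  assignment <- match(assignment, sort(unique(assignment)))
  prev_hard <- NULL
  converged <- FALSE
  iter <- 0L
  n_moved <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    K_cur <- max(assignment)
    models <- lapply(seq_len(K_cur), function(i)
      fit_cluster_model(X, as.numeric(assignment == i), n_u, r, n_t, N))
    pz <- do.call(rbind, lapply(models, function(m)
      compute_membership(X, m$subject, m$p, m$q, prior)$pz))
    hard <- assign_clusters(pz)
    new_assignment <- match(hard$assignment, hard$surviving)
    pz <- pz[hard$surviving, , drop = FALSE]

    if (verbose)
      message(sprintf(
        "iter %d: K = %d -> %d, moved %d, Q = %.4g",
        iter, K_cur, length(hard$surviving), n_moved,
        theme_score(lapply(models, function(m) m$alpha[m$subject]))))

    if (identical(new_assignment, prev_hard)) {
      assignment <- new_assignment
      converged <- TRUE
      break
    }
    prev_hard <- new_assignment
    assignment <- new_assignment
    if (nrow(pz) == 1L) {
      # a single cluster cannot change under argmax; stable by construction
      converged <- TRUE
      break
    }
    perturbed <- reassign_lowest(pz, new_assignment, reassign_frac)
    n_moved <- sum(perturbed != new_assignment)
    assignment <- match(perturbed, sort(unique(perturbed)))
  }

  # reported models are refit from the final assignment so the subject
  # terms, alpha and theme score all describe the partition being returned
  sizes <- tabulate(assignment)
  clusters <- lapply(seq_len(max(assignment)), function(i) {
    m <- fit_cluster_model(X, as.numeric(assignment == i), n_u, r, n_t, N)
    sel <- m$subject
    list(terms = names(m$alpha)[sel],
         alpha = m$alpha[sel],
         p = m$p[sel],
         q = m$q[sel],
         size = sizes[i],
         n_s = m$n_s)
  })
  list(cluster = stats::setNames(assignment, inc$doc_ids),
       clusters = clusters,
       Q = theme_score(lapply(clusters, function(cl) cl$alpha)),
       n_iterations = iter,
       converged = converged,
       seed = seed,
       initial_k = k,
       final_k = length(clusters))
}

#' Thematic clustering of documents by EM subject-term selection
#'
#' Fits a hard clustering of documents in which every cluster (a "theme") is
#' described by its `n_u` subject terms — the terms whose occurrence pattern
#' gains most expected log-likelihood when modelled with theme-specific
#' in/out probabilities (p_t, q_t) instead of the corpus background rate
#' r_t.  The classification-EM loop alternates: (1) per-cluster estimation
#' of p_t, q_t and the gain alpha_t from the current hard partition;
#' (2) selection of the top-`n_u` alpha terms as the cluster's subject
#' terms; (3) posterior membership pz_d of every document under each
#' cluster's Bernoulli model; (4) hard argmax reassignment, pruning
#' clusters that win no document (so the final cluster count is
#' data-driven, at most `k`); (5) on non-converged iterations, re-seating
#' each cluster's weakest `reassign_frac` members into their second-best
#' cluster to escape local optima.  Convergence is exact equality of
#' consecutive argmax assignments.
#'
#' With `restarts > 1` the model is refit from `restarts` seeded random
#' initial partitions and the fit with the largest theme score
#' \eqn{Q = \sum_i \sum_{t \in U_i} \alpha_t^2} is returned — the model
#' selection rule across restarts.
#'
#' @param x An `"incidence"` object from [build_incidence()], or a
#'   data.frame of documents (`doc_id`, `text`) which is passed through
#'   [build_incidence()] with default settings.
#' @param k Initial number of clusters.
#' @param n_u Number of subject terms per cluster.
#' @param prior Prior membership probability pr_d (scalar in (0,1)); 0.5 is
#'   neutral and removes the prior's influence on the evidence.
#' @param restarts Number of seeded random restarts; the best theme score
#'   wins (ties: lowest seed).
#' @param seed Base integer seed; restart j uses `seed + j - 1`.  Drawn from
#'   the session RNG when `NULL`.
#' @param max_iter Safety cap on EM iterations per restart.
#' @param reassign_frac Per-cluster fraction of weakest members re-seated
#'   each non-converged iteration (floor of fraction times cluster size).
#' @param verbose Print a per-iteration progress line?
#' @return An object of class `"theme_clust"`: a list with `cluster` (named
#'   integer assignment per document), `clusters` (per surviving cluster:
#'   subject `terms`, their `alpha`, `p`, `q`, cluster `size`, `n_s`), theme
#'   score `Q`, `n_iterations`, `converged`, `seed` (of the winning
#'   restart), `initial_k`, `final_k`, and `restart_Q` (named theme-score
#'   trace over all restarts).
#' @seealso [theme_score()], [nmi()], [select_title()], [planted_corpus()]
#' @export
#' @examples
#' corp <- planted_corpus(n_themes = 2, docs_per_theme = 30,
#'                        theme_vocab_size = 10, background_vocab_size = 50,
#'                        p_in = 0.8, p_out = 0.02, seed = 7)
#' inc <- build_incidence(corp$documents, stopwords = character(),
#'                        min_doc_freq = 2, bigrams = FALSE)
#' fit <- theme_cluster(inc, k = 2, n_u = 15, restarts = 3, seed = 1)
#' fit
#' nmi(fit$cluster, corp$labels)
theme_cluster <- function(x, k = 50L, n_u = 100L, prior = 0.5,
                          restarts = 1L, seed = NULL, max_iter = 100L,
                          reassign_frac = 0.01, verbose = FALSE) {
  if (is.data.frame(x)) x <- build_incidence(x)
  stopifnot(inherits(x, "incidence"),
            k >= 1L, n_u >= 1L, restarts >= 1L, max_iter >= 1L,
            prior > 0, prior < 1, reassign_frac >= 0, reassign_frac < 1)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - restarts, 1L)
  seeds <- seed + seq_len(restarts) - 1L

  runs <- lapply(seeds, function(s)
    theme_em_once(x, k, n_u, prior, s, max_iter, reassign_frac, verbose))
  qs <- vapply(runs, function(rn) rn$Q, numeric(1))
  best <- runs[[which.max(qs)]]
  best$restart_Q <- stats::setNames(qs, seeds)
  best$call <- match.call()
  class(best) <- "theme_clust"
  best
}

#' Theme score of a clustering
#'
#' The model-selection criterion across random restarts: the sum over
#' clusters of the squared alpha gains of their selected subject terms,
#' \eqn{Q = \sum_i \sum_{t \in U_i} \alpha_t^2}.  Invariant to cluster
#' relabelling.
#'
#' @param x A `"theme_clust"` fit, or a list of numeric vectors (the
#'   selected alpha values of each cluster).
#' @return A single number Q >= 0.
#' @export
theme_score <- function(x) {
  if (inherits(x, "theme_clust"))
    x <- lapply(x$clusters, function(cl) cl$alpha)
  stopifnot(is.list(x), length(x) >= 1L)
  sum(vapply(x, function(a) sum(a^2), numeric(1)))
}

#' @export
print.theme_clust <- function(x, n_terms = 5L, ...) {
  cat("Thematic clustering\n")
  cat(sprintf("  %d documents, %d clusters (initial k = %d)\n",
              length(x$cluster), x$final_k, x$initial_k))
  cat(sprintf("  theme score Q = %.4g; %s in %d iterations; seed %d",
              x$Q, if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$seed))
  if (length(x$restart_Q) > 1L)
    cat(sprintf(" (best of %d restarts)", length(x$restart_Q)))
  cat("\n  top subject terms:\n")
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("    [%d] (%d docs) %s\n", i, cl$size,
                paste(utils::head(cl$terms, n_terms), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.theme_clust <- function(object, ...) {
  structure(list(
    n_docs = length(object$cluster),
    initial_k = object$initial_k,
    final_k = object$final_k,
    sizes = vapply(object$clusters, function(cl) cl$size, numeric(1)),
    Q = object$Q,
    converged = object$converged,
    n_iterations = object$n_iterations,
    restart_Q = object$restart_Q,
    top_terms = lapply(object$clusters,
                       function(cl) utils::head(cl$terms, 10L))),
    class = "summary.theme_clust")
}

#' @export
print.summary.theme_clust <- function(x, ...) {
  cat(sprintf(
    "Thematic clustering of %d documents: %d -> %d clusters, Q = %.4g\n",
    x$n_docs, x$initial_k, x$final_k, x$Q))
  cat(sprintf("Converged: %s (%d iterations)\n",
              if (x$converged) "yes" else "no", x$n_iterations))
  if (length(x$restart_Q) > 1L)
    cat(sprintf("Theme score over %d restarts: min %.4g, median %.4g, max %.4g\n",
                length(x$restart_Q), min(x$restart_Q),
                stats::median(x$restart_Q), max(x$restart_Q)))
  cat("Cluster sizes:", paste(x$sizes, collapse = ", "), "\n")
  for (i in seq_along(x$top_terms))
    cat(sprintf("  [%d] %s\n", i, paste(x$top_terms[[i]], collapse = ", ")))
  invisible(x)
}

#' @export
coef.theme_clust <- function(object, ...) {
  lapply(object$clusters, function(cl) cl$alpha)
}

#' Posterior membership of (new) documents under a fitted theme model
#'
#' Scores documents against each fitted cluster's Bernoulli subject-term
#' model.  Subject terms absent from the new vocabulary count as
#' non-occurring.
#'
#' @param object A `"theme_clust"` fit.
#' @param newdata An `"incidence"` object (terms matched by name).
#' @param type `"class"` for hard argmax labels, `"posterior"` for the
#'   documents-by-clusters matrix of pz_d.
#' @param prior Prior membership probability used in scoring.
#' @param ... Unused.
#' @return Integer vector of cluster labels, or a numeric matrix.
#' @export
predict.theme_clust <- function(object, newdata,
                                type = c("class", "posterior"),
                                prior = 0.5, ...) {
  type <- match.arg(type)
  stopifnot(inherits(newdata, "incidence"))
  X <- newdata$incidence
  pz <- vapply(object$clusters, function(cl) {
    w <- log(cl$p * (1 - cl$q) / (cl$q * (1 - cl$p)))
    hit <- match(cl$terms, newdata$terms)
    ok <- !is.na(hit)
    ev <- if (any(ok))
      as.vector(Matrix::crossprod(X[hit[ok], , drop = FALSE], w[ok]))
    else rep(0, ncol(X))
    cprime <- sum(log((1 - cl$p) / (1 - cl$q)))
    stats::plogis(log(prior / (1 - prior)) + ev + cprime)
  }, numeric(ncol(X)))
  pz <- matrix(pz, nrow = ncol(X),
               dimnames = list(newdata$doc_ids, NULL))
  if (type == "posterior") return(pz)
  stats::setNames(max.col(pz, ties.method = "first"), newdata$doc_ids)
}

#' @export
plot.theme_clust <- function(x, ...) {
  alphas <- lapply(x$clusters, function(cl) sort(cl$alpha, decreasing = TRUE))
  len <- max(lengths(alphas))
  mat <- vapply(alphas, function(a) c(a, rep(NA_real_, len - length(a))),
                numeric(len))
  graphics::matplot(mat, type = "l", lty = 1,
                    xlab = "subject-term rank",
                    ylab = expression(alpha[t]),
                    main = sprintf("Subject-term gain profiles (Q = %.3g)",
                                   x$Q), ...)
  invisible(x)
}
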