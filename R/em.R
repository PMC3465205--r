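# Probability clamp keeping every log finite.  Hard assignments make
# empirical frequencies of exactly 0 or 1 routine, so all of p_t, q_t, r_t
# pass through this before any logarithm.
.prob_eps <- 1e-6

clamp_prob <- function(x) pmin(pmax(x, .prob_eps), 1 - .prob_eps)

# Accept an "incidence" object or a bare (sparse) term x document matrix.
incidence_matrix <- function(relation) {
  if (inherits(relation, "incidence")) relation$incidence else relation
}

#' Background term occurrence rates
#'
#' The background model gives every term t a single corpus-wide occurrence
#' probability r_t = n_t / N, clamped away from 0 and 1.
#'
#' @param relation An `"incidence"` object (or term-by-document 0/1 matrix).
#' @return Named numeric vector r_t.
#' @export
estimate_background <- function(relation) {
  X <- incidence_matrix(relation)
  if (ncol(X) == 0L) stop("empty relation")
  clamp_prob(Matrix::rowSums(X) / ncol(X))
}

#' Per-cluster term occurrence parameters
#'
#' Given one cluster's per-document membership weights pz_d in \[0, 1\]
#' (binary for a hard partition), estimates for every term its in-theme
#' occurrence probability p_t and out-of-theme probability q_t:
#' \deqn{p_t = \sum_d \delta_{td} pz_d / \sum_d pz_d, \quad
#'       q_t = \sum_d \delta_{td} (1 - pz_d) / \sum_d (1 - pz_d),}
#' both clamped into (0, 1).  Also returns the soft cluster size
#' n_s = sum(pz) and soft co-occurrence n_st per term, which feed the
#' subject-term gain [compute_alpha()].
#'
#' @param relation An `"incidence"` object (or 0/1 term x document matrix).
#' @param posterior Numeric vector of membership weights, one per document,
#'   each in \[0, 1\].
#' @return List with `p` (p_t), `q` (q_t), `n_s`, `n_st`.
#' @export
estimate_cluster_params <- function(relation, posterior) {
  X <- incidence_matrix(relation)
  N <- ncol(X)
  stopifnot(length(posterior) == N, all(posterior >= 0), all(posterior <= 1))
  n_s <- sum(posterior)
  if (n_s <= 0 || n_s >= N)
    stop("degenerate cluster: zero membership mass inside or outside")
  n_st <- as.vector(X %*% posterior)
  n_t <- Matrix::rowSums(X)
  p <- clamp_prob(n_st / n_s)
  q <- clamp_prob((n_t - n_st) / (N - n_s))
  names(p) <- names(q) <- names(n_st) <- rownames(X)
  list(p = p, q = q, n_s = n_s, n_st = n_st)
}

#' Subject-term gain alpha
#'
#' alpha_t is the gain in expected complete-data log-likelihood from
#' modelling term t with theme-specific probabilities (p_t, q_t) rather
#' than the background rate r_t:
#' \deqn{\alpha_t = n_{st}\ln\frac{p_t}{q_t}
#'   + (n_s - n_{st})\ln\frac{1-p_t}{1-q_t}
#'   + (n_t - n_{st})\ln\frac{q_t}{r_t}
#'   + (N - n_t - n_s + n_{st})\ln\frac{1-q_t}{1-r_t}.}
#' Terms with the largest alpha_t are the cluster's subject terms.
#'
#' @param p,q,r Clamped probabilities per term (in-theme, out-of-theme,
#'   background).
#' @param n_s Soft cluster size.
#' @param n_st Soft co-occurrence per term.
#' @param n_t Document frequency per term.
#' @param n_docs Total number of documents N.
#' @return Numeric vector alpha_t.
#' @export
compute_alpha <- function(p, q, r, n_s, n_st, n_t, n_docs) {
  n_st * log(p / q) +
    (n_s - n_st) * log((1 - p) / (1 - q)) +
    (n_t - n_st) * log(q / r) +
    (n_docs - n_t - n_s + n_st) * log((1 - q) / (1 - r))
}

#' Select the subject terms of a cluster
#'
#' The `n_u` terms with largest alpha (all terms if fewer exist), returned
#' as indices in descending alpha order.  Ties are broken by lexicographic
#' term order so runs are reproducible.
#'
#' @param alpha Numeric vector of gains, named by term (names used for tie
#'   breaking; falls back to index order when unnamed).
#' @param n_u Number of subject terms to keep (>= 1).
#' @return Integer vector of term indices, descending alpha.
#' @export
select_subject_terms <- function(alpha, n_u) {
  stopifnot(n_u >= 1L)
  keys <- names(alpha)
  if (is.null(keys)) keys <- seq_along(alpha)
  ord <- order(-alpha, keys)
  ord[seq_len(min(n_u, length(alpha)))]
}

#' Posterior theme membership of every document
#'
#' For one cluster with subject-term set U and clamped parameters p, q,
#' computes for every document the log-odds evidence
#' \deqn{score_d = \ln\frac{pr_d}{1-pr_d}
#'   + \sum_{t \in U} \delta_{td} \ln\frac{p_t(1-q_t)}{q_t(1-p_t)}}
#' and the exact Bayes posterior under the Bernoulli occurrence model
#' restricted to U,
#' \deqn{pz_d = \mathrm{logit}^{-1}(score_d + C'), \quad
#'       C' = \sum_{t \in U} \ln\frac{1-p_t}{1-q_t}.}
#'
#' @param relation An `"incidence"` object (or 0/1 term x document matrix).
#' @param subject Integer indices of the subject terms U (rows of the
#'   incidence matrix).
#' @param p,q Full-length clamped probability vectors (indexed by `subject`).
#' @param prior Prior membership probability pr_d, a scalar in (0,1) or a
#'   per-document vector.
#' @return List with `score` and `pz`, one value per document.
#' @export
compute_membership <- function(relation, subject, p, q, prior = 0.5) {
  X <- incidence_matrix(relation)
  stopifnot(length(subject) >= 1L, all(prior > 0), all(prior < 1))
  pu <- p[subject]
  qu <- q[subject]
  w <- log(pu * (1 - qu) / (qu * (1 - pu)))
  score <- log(prior / (1 - prior)) +
    as.vector(Matrix::crossprod(X[subject, , drop = FALSE], w))
  cprime <- sum(log((1 - pu) / (1 - qu)))
  pz <- stats::plogis(score + cprime)
  names(score) <- names(pz) <- colnames(X)
  list(score = score, pz = pz)
}

#' Hard cluster assignment from posterior memberships
#'
#' Assigns each document to the cluster with the highest posterior pz_d
#' (ties: lowest cluster index).  Clusters that win no document are marked
#' for removal — this is how the effective number of clusters shrinks.
#'
#' @param pz Numeric matrix, clusters x documents, of posteriors.
#' @return List with `assignment` (cluster row index per document) and
#'   `surviving` (row indices that received at least one document).
#' @export
assign_clusters <- function(pz) {
  stopifnot(is.matrix(pz), nrow(pz) >= 1L)
  assignment <- max.col(t(pz), ties.method = "first")
  list(assignment = assignment,
       surviving = sort(unique(assignment)))
}

#' Perturb a hard assignment by re-seating the weakest members
#'
#' For each cluster V_i, the `floor(fraction * |V_i|)` member documents with
#' the lowest pz_d in that cluster are moved to the cluster giving them the
#' second-highest posterior.  A shuffling step between EM sweeps that helps
#' escape poor local optima; a no-op when fewer than two clusters survive
#' or the floor is zero.
#'
#' @param pz Numeric matrix, clusters x documents, of posteriors.
#' @param assignment Integer vector of current cluster per document.
#' @param fraction Proportion in \[0, 1) of each cluster to move.
#' @return Integer vector of perturbed assignments.
#' @export
reassign_lowest <- function(pz, assignment, fraction = 0.01) {
  stopifnot(fraction >= 0, fraction < 1)
  clusters <- sort(unique(assignment))
  if (length(clusters) < 2L || fraction == 0) return(assignment)
  out <- assignment
  for (i in clusters) {
    members <- which(assignment == i)
    k <- floor(fraction * length(members))
    if (k < 1L) next
    ord <- members[order(pz[i, members], members)]
    for (d in ord[seq_len(k)]) {
      # second-highest among surviving clusters only; ties -> lowest index
      ranked <- clusters[order(-pz[clusters, d], clusters)]
      out[d] <- ranked[2L]
    }
  }
  out
}
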