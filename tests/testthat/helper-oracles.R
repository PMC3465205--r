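# Independent oracles used to verify the closed-form implementations.
# Each is a direct, brute-force evaluation of the defining quantity and
# deliberately shares no code with the package internals.

# Exact Bayes posterior that a document belongs to the theme, from the full
# Bernoulli likelihood over the subject terms: prior * prod(p^d (1-p)^(1-d))
# against (1-prior) * prod(q^d (1-q)^(1-d)).
oracle_posterior <- function(delta, p, q, prior) {
  lik_in <- prior * prod(ifelse(delta == 1, p, 1 - p))
  lik_out <- (1 - prior) * prod(ifelse(delta == 1, q, 1 - q))
  lik_in / (lik_in + lik_out)
}

# Gain of promoting term t to a subject term: the expected log-likelihood
# of its occurrence pattern under the subject model (rate p within the
# theme, q outside) minus the non-subject model (q within the theme, the
# background rate r outside), summed document by document with posterior
# weights.
oracle_alpha <- function(delta_t, pz, p, q, r) {
  as_subject <-
    sum(pz * (delta_t * log(p) + (1 - delta_t) * log(1 - p))) +
    sum((1 - pz) * (delta_t * log(q) + (1 - delta_t) * log(1 - q)))
  as_nonsubject <-
    sum(pz * (delta_t * log(q) + (1 - delta_t) * log(1 - q))) +
    sum((1 - pz) * (delta_t * log(r) + (1 - delta_t) * log(1 - r)))
  as_subject - as_nonsubject
}

# Reference NMI in the entropy form I(X;Y) / sqrt(H(X) H(Y)) computed from
# joint relative frequencies.
oracle_nmi <- function(a, b) {
  joint <- table(a, b) / length(a)
  px <- rowSums(joint)
  py <- colSums(joint)
  mi <- 0
  for (h in seq_along(px)) for (l in seq_along(py))
    if (joint[h, l] > 0)
      mi <- mi + as.numeric(joint[h, l] * log(joint[h, l] / (px[h] * py[l])))
  hx <- -sum(px * log(px))
  hy <- -sum(py * log(py))
  mi / sqrt(hx * hy)
}

# Upper-tail hypergeometric probability by direct combinatorial enumeration:
# P(X >= k) when drawing n from a corpus of size N containing K labelled.
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Small random incidence instance for oracle-equivalence loops.
random_instance <- function(n_docs_max = 6L, n_terms_max = 5L) {
  nd <- sample(2:n_docs_max, 1)
  nt <- sample(1:n_terms_max, 1)
  delta <- matrix(rbinom(nt * nd, 1, runif(1, 0.2, 0.8)), nrow = nt,
                  dimnames = list(sprintf("w%02d", seq_len(nt)), NULL))
  list(delta = delta, n_docs = nd, n_terms = nt)
}
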