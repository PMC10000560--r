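# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive elementwise loops so they share no code with the
# vectorized implementations they check.

# Naive Btm log-likelihood: triple loop over (i, j, k).
oracle_btm_loglik <- function(pi, e, b) {
  m <- ncol(b)
  k <- length(pi)
  ll <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (b[i, j] == 0) next
      p <- 0
      for (kk in seq_len(k)) p <- p + pi[kk] * e[kk, i] * e[kk, j]
      ll <- ll + b[i, j] * log(p)
    }
  }
  ll
}

# Naive Btm E-step, written straight from the update equations:
# p(k|ij) = pi_k e_k(i) e_k(j) / sum_k', E_k(i) = sum_j B_ij p(k|ji) + B_ji p(k|ij).
oracle_btm_e_step <- function(pi, e, b) {
  m <- ncol(b)
  kk <- length(pi)
  resp <- array(0, c(kk, m, m))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      denom <- 0
      for (k in seq_len(kk)) denom <- denom + pi[k] * e[k, i] * e[k, j]
      for (k in seq_len(kk)) resp[k, i, j] <- pi[k] * e[k, i] * e[k, j] / denom
    }
  }
  E <- matrix(0, kk, m)
  for (k in seq_len(kk)) {
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        E[k, i] <- E[k, i] + b[i, j] * resp[k, j, i] + b[j, i] * resp[k, i, j]
      }
    }
  }
  list(E = E, A = rowSums(E))
}

# Naive Mix likelihood: direct evaluation of the printed product-sum.
oracle_mix_loglik <- function(w, pi, e, v) {
  n <- nrow(v)
  ll <- 0
  for (s in seq_len(n)) {
    tot <- 0
    for (l in seq_along(w)) {
      term <- w[l]
      for (j in seq_len(ncol(v))) {
        pj <- sum(pi[l, ] * e[, j])
        term <- term * pj^v[s, j]
      }
      tot <- tot + term
    }
    ll <- ll + log(tot)
  }
  ll
}

random_simplex <- function(n) {
  x <- runif(n)
  x / sum(x)
}

# Random small Btm instance (model + biterm matrix from a random catalog).
random_btm_instance <- function(m = 4, k = 2, n = 5, max_count = 4) {
  counts <- matrix(rpois(n * m, 1.5), n, m)
  counts[counts > max_count] <- max_count
  b <- cohort_biterms(counts)
  pi <- random_simplex(k)
  e <- t(vapply(seq_len(k), function(i) random_simplex(m), numeric(m)))
  list(pi = pi, e = e, b = b,
    model = structure(
      list(pi = pi, e = e, k = k, categories = NULL),
      class = "btm_model"
    ))
}

toy_catalog <- function(counts, categories = NULL) {
  counts <- as.matrix(counts)
  if (is.null(categories)) categories <- sprintf("cat%03d", seq_len(ncol(counts)))
  colnames(counts) <- categories
  mutation_catalog(counts, categories = categories)
}

# Catalog with canonical SBS-96 categories and given row sums, spread over
# random categories.
random_sbs_catalog <- function(n, mean_burden = 10) {
  cats <- sbs96_categories()
  counts <- t(vapply(seq_len(n), function(i) {
    as.integer(stats::rmultinom(1, rpois(1, mean_burden), random_simplex(96)))
  }, integer(96)))
  colnames(counts) <- cats
  mutation_catalog(counts)
}

# Best label-matching accuracy between true and inferred cluster labels.
label_match_accuracy <- function(truth, inferred, l) {
  perms <- btmsig:::permutations_of(seq_len(l), l)
  best <- 0
  for (p in perms) {
    best <- max(best, mean(p[inferred] == truth))
  }
  best
}

# Per-signature total-variation distances after the optimal assignment of
# learned to true signatures (cosine-based assignment).
matched_tv <- function(e_learned, e_true) {
  cs <- btmsig:::cosine_matrix(e_learned, e_true)
  assign <- btmsig:::best_assignment(cs)
  vapply(seq_len(nrow(e_learned)), function(i) {
    total_variation(e_learned[i, ], e_true[assign[i], ])
  }, 0)
}

matched_assignment <- function(e_learned, e_true) {
  btmsig:::best_assignment(btmsig:::cosine_matrix(e_learned, e_true))
}
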