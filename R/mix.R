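# Mix: a mixture of multinomial mixture models. Samples are soft-clustered
# into L clusters; each cluster l has its own exposure vector pi_l over K
# signatures shared by all clusters. A sample's counts are multinomial
# draws from the cluster's mixture distribution sum_i pi_li e_i(.). The
# likelihood (multinomial coefficient omitted, constant in the parameters):
#   Pr(V | w, pi, e) = prod_n sum_l w_l prod_j [ sum_i pi_li e_i(j) ] ^ V_nj
# fitted by EM with two levels of latent structure: the cluster of each
# sample, and the signature of each mutation within the cluster. One
# iteration costs O(N L K M).

new_mix_model <- function(w, pi, e, seed = NULL, train_ll = NA_real_,
                          categories = colnames(e), ll_trace = NULL) {
  structure(
    list(
      w = as.numeric(w), pi = as.matrix(pi), e = e,
      l = length(w), k = nrow(e), categories = categories,
      seed = seed, train_ll = train_ll, ll_trace = ll_trace
    ),
    class = "mix_model"
  )
}

#' @export
print.mix_model <- function(x, ...) {
  cat(sprintf(
    "Mix model: L = %d clusters, K = %d shared signatures, M = %d categories\n",
    x$l, x$k, ncol(x$e)
  ))
  cat(sprintf(
    "  cluster weights: %s\n",
    paste(sprintf("%.3f", x$w), collapse = ", ")
  ))
  if (is.finite(x$train_ll)) {
    cat(sprintf("  training log-likelihood: %.4f\n", x$train_ll))
  }
  invisible(x)
}

mix_check_dims <- function(model, v) {
  if (ncol(model$e) != ncol(v)) {
    abort(sprintf(
      "model has %d categories but catalog has %d", ncol(model$e), ncol(v)
    ))
  }
}

# N x L matrix of per-sample per-cluster log-likelihood terms
# log w_l + sum_j V_nj log( sum_i pi_li e_i(j) ).
mix_cluster_loglik <- function(model, v) {
  pcat <- model$pi %*% model$e # L x M cluster category distributions
  lp <- log(pmax(pcat, .Machine$double.xmin))
  s <- v %*% t(lp)
  if (any(pcat <= 0)) {
    # a positive count on a zero-probability category is impossible, not
    # merely unlikely: force exact -Inf for those (sample, cluster) pairs
    impossible <- ((v > 0) %*% t(pcat <= 0)) > 0
    s[impossible] <- -Inf
  }
  sweep(s, 2L, log(model$w), `+`)
}

#' Log-likelihood of a catalog under a Mix model
#'
#' Computed in log space with a log-sum-exp over clusters; the multinomial
#' coefficient is omitted. Applies unchanged to held-out catalogs (clusters
#' are marginalized, nothing is refitted), so it doubles as the held-out
#' score; an empty catalog scores 0.
#'
#' @param model A `mix_model`.
#' @param catalog A catalog tibble or count matrix.
#' @return A single number (may be `-Inf` if a positive count falls on a
#'   category with zero probability in every cluster; the signature floor
#'   used in training prevents this for fitted models).
#' @export
mix_log_likelihood <- function(model, catalog) {
  v <- if (is.data.frame(catalog)) catalog_matrix(catalog) else as.matrix(catalog)
  mix_check_dims(model, v)
  if (nrow(v) == 0) return(0)
  sum(row_logsumexp(mix_cluster_loglik(model, v)))
}

#' @rdname mix_log_likelihood
#' @export
mix_heldout_log_likelihood <- function(model, catalog) {
  mix_log_likelihood(model, catalog)
}

#' Per-sample cluster responsibilities under a Mix model
#'
#' @inheritParams mix_log_likelihood
#' @return Tibble with `sample_id`, one `cluster_*` column of posterior
#'   probability per cluster, and the hard `cluster` assignment (argmax).
#' @export
mix_responsibilities <- function(model, catalog) {
  v <- if (is.data.frame(catalog)) catalog_matrix(catalog) else as.matrix(catalog)
  mix_check_dims(model, v)
  s <- mix_cluster_loglik(model, v)
  g <- exp(s - row_logsumexp(s))
  g <- g / rowSums(g)
  colnames(g) <- paste0("cluster_", seq_len(ncol(g)))
  out <- tibble::as_tibble(as.data.frame(g, optional = TRUE))
  dplyr::bind_cols(
    tibble::tibble(sample_id = rownames(v) %||% as.character(seq_len(nrow(v)))),
    out,
    tibble::tibble(cluster = max.col(g, ties.method = "first"))
  )
}

mix_random_init <- function(l, k, m, categories = NULL) {
  w <- rdirichlet1(l, 1)
  pi <- t(vapply(seq_len(l), function(i) rdirichlet1(k, 1), numeric(k)))
  if (k == 1) pi <- matrix(1, l, 1)
  e <- t(vapply(seq_len(k), function(i) rdirichlet1(m, 1), numeric(m)))
  e <- floor_rows(e)
  colnames(e) <- categories
  new_mix_model(w = w, pi = pi, e = e)
}

# One EM pass over the catalog count matrix v.
mix_em_iterate <- function(model, v, update_e = TRUE, floor_eps = 1e-12) {
  l <- model$l
  k <- model$k
  m <- ncol(model$e)
  s <- mix_cluster_loglik(model, v)
  lse <- row_logsumexp(s)
  gamma <- exp(s - lse)
  gamma <- gamma / rowSums(gamma)
  ll <- sum(lse)
  cw <- t(gamma) %*% v # L x M expected counts per cluster/category
  pcat <- model$pi %*% model$e
  pi_new <- matrix(0, l, k)
  e_acc <- matrix(0, k, m)
  for (cl in seq_len(l)) {
    q <- (model$pi[cl, ] * model$e) / rep(pcat[cl, ], each = k) # K x M
    contrib <- q * rep(cw[cl, ], each = k)
    pi_new[cl, ] <- rowSums(contrib)
    e_acc <- e_acc + contrib
  }
  w_new <- floor_vec(colSums(gamma) / nrow(v), floor_eps)
  pi_new <- floor_rows(pi_new, floor_eps)
  e_new <- if (update_e) floor_rows(e_acc, floor_eps) else model$e
  colnames(e_new) <- colnames(model$e)
  out <- new_mix_model(w = w_new, pi = pi_new, e = e_new,
    categories = model$categories)
  out$last_ll <- ll
  out
}

mix_em_run <- function(model, v, iters, update_e = TRUE, trace = FALSE,
                       floor_eps = 1e-12, tol = NULL) {
  ll_trace <- if (trace) numeric(iters) else NULL
  ll <- NA_real_
  for (it in seq_len(iters)) {
    new <- mix_em_iterate(model, v, update_e = update_e, floor_eps = floor_eps)
    prev_ll <- ll
    ll <- new$last_ll # LL of the model entering the iteration
    if (trace) ll_trace[it] <- ll
    model <- new
    if (!is.null(tol) && is.finite(prev_ll) &&
      abs(ll - prev_ll) <= tol * abs(prev_ll)) {
      if (trace) ll_trace <- ll_trace[seq_len(it)]
      break
    }
  }
  model$train_ll <- mix_log_likelihood(model, v)
  model$ll_trace <- if (trace) c(ll_trace, model$train_ll) else NULL
  model$last_ll <- NULL
  model
}

#' Fit a Mix model by multi-seed EM
#'
#' Same two-stage protocol as [train_btm()]: `n_seeds` random
#' initializations run for `burn_iters` iterations each, the best continues
#' for `final_iters`. When `fixed_signatures` is supplied the signature
#' matrix is held fixed and only the cluster weights and exposures are
#' learned (refit mode).
#'
#' @param catalog A catalog tibble or count matrix.
#' @param k Number of shared signatures.
#' @param l Number of sample clusters.
#' @inheritParams train_btm
#' @param fixed_signatures Optional signature set tibble; when given, `e`
#'   is fixed to it (floored at `floor_eps`) and `k` is taken from it.
#' @return A fitted `mix_model`.
#' @export
train_mix <- function(catalog, k, l, n_seeds = 10, burn_iters = 100,
                      final_iters = 500, seed = 1, fixed_signatures = NULL,
                      trace = FALSE, tol = NULL, floor_eps = 1e-12) {
  stopifnot(k >= 1, l >= 1)
  v <- if (is.data.frame(catalog)) catalog_matrix(catalog) else {
    m0 <- as.matrix(catalog); validate_counts(m0); m0
  }
  if (l > nrow(v)) {
    abort(sprintf("l = %d clusters exceeds N = %d samples", l, nrow(v)))
  }
  e_fixed <- NULL
  if (!is.null(fixed_signatures)) {
    e_fixed <- floor_rows(signature_matrix(fixed_signatures), floor_eps)
    if (ncol(e_fixed) != ncol(v)) {
      abort("fixed signatures and catalog have different category sets")
    }
    k <- nrow(e_fixed)
  }
  seeds <- spawn_seeds(seed, n_seeds)
  best <- NULL
  for (s in seeds) {
    init <- with_rng(s, mix_random_init(l, k, ncol(v), colnames(v)))
    if (!is.null(e_fixed)) init$e <- e_fixed
    fit <- mix_em_run(init, v, burn_iters, update_e = is.null(e_fixed),
      floor_eps = floor_eps, tol = tol)
    if (is.null(best) || fit$train_ll > best$train_ll) best <- fit
  }
  out <- mix_em_run(best, v, final_iters, update_e = is.null(e_fixed),
    trace = trace, floor_eps = floor_eps, tol = tol)
  out$seed <- seed
  out$n_seeds <- n_seeds
  out$burn_iters <- burn_iters
  out$final_iters <- final_iters
  out$categories <- colnames(v)
  out
}

#' Bayesian information criterion for a fitted Mix model
#'
#' `BIC = p * log(n_obs) - 2 * LL` with free-parameter count
#' `p = (L - 1) + L (K - 1) + K (M - 1)`; lower is better. The observation
#' count defaults to the number of samples (the likelihood is a product
#' over samples); `observations = "mutations"` uses the total mutation
#' count instead.
#'
#' @inheritParams mix_log_likelihood
#' @param observations `"samples"` (default) or `"mutations"`.
#' @return The BIC value (a single number).
#' @export
mix_bic <- function(model, catalog, observations = c("samples", "mutations")) {
  observations <- match.arg(observations)
  v <- if (is.data.frame(catalog)) catalog_matrix(catalog) else as.matrix(catalog)
  n_obs <- if (observations == "samples") nrow(v) else sum(v)
  p <- mix_n_parameters(model$l, model$k, ncol(model$e))
  p * log(n_obs) - 2 * mix_log_likelihood(model, v)
}

mix_n_parameters <- function(l, k, m) {
  (l - 1) + l * (k - 1) + k * (m - 1)
}
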