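# Biterm topic model (Btm). Each biterm (an ordered pair of distinct
# mutation instances co-occurring in a patient) is assumed to arise from a
# single mutational process: a signature k is drawn from a global exposure
# vector pi, then the two mutation categories i and j are drawn
# independently from signature k. The observed-data likelihood over a
# biterm matrix B is
#     Pr(B | pi, e) = prod_ij [ sum_k pi_k e_k(i) e_k(j) ] ^ B_ij
# fitted by EM. One EM iteration costs O(K M^2): it touches only the M x M
# biterm matrix, never the N samples.

new_btm_model <- function(pi, e, seed = NULL, train_ll = NA_real_,
                          categories = colnames(e), ll_trace = NULL) {
  structure(
    list(
      pi = as.numeric(pi), e = e, k = length(pi),
      categories = categories, seed = seed, train_ll = train_ll,
      ll_trace = ll_trace
    ),
    class = "btm_model"
  )
}

#' @export
print.btm_model <- function(x, ...) {
  cat(sprintf(
    "Biterm topic model: K = %d signatures over M = %d categories\n",
    x$k, ncol(x$e)
  ))
  cat(sprintf(
    "  global exposures: %s\n",
    paste(sprintf("%.3f", x$pi), collapse = ", ")
  ))
  if (is.finite(x$train_ll)) {
    cat(sprintf("  training log-likelihood: %.4f\n", x$train_ll))
  }
  invisible(x)
}

as_biterm_matrix <- function(b) {
  if (is.data.frame(b)) b <- cohort_biterms(b)
  b <- as.matrix(b)
  if (nrow(b) != ncol(b)) abort("biterm matrix must be square")
  b
}

check_model_dims <- function(model, b) {
  if (ncol(model$e) != ncol(b)) {
    abort(sprintf(
      "model has %d categories but biterm matrix has %d",
      ncol(model$e), ncol(b)
    ))
  }
}

# Mixture probability of each (i, j) pair: P_ij = sum_k pi_k e_k(i) e_k(j).
btm_pair_probs <- function(pi, e) {
  crossprod(e, pi * e) # t(e) %*% diag(pi) %*% e, M x M
}

#' Log-likelihood of a biterm matrix under a Btm model
#'
#' @param model A `btm_model`.
#' @param b An M x M biterm matrix (or a catalog tibble, converted with
#'   [cohort_biterms()]).
#' @return `sum_ij B[i,j] * log sum_k pi_k e_k(i) e_k(j)`; `-Inf` if some
#'   observed biterm has zero probability under every signature.
#' @export
btm_log_likelihood <- function(model, b) {
  b <- as_biterm_matrix(b)
  check_model_dims(model, b)
  p <- btm_pair_probs(model$pi, model$e)
  idx <- b > 0
  if (!any(idx)) return(0)
  sum(b[idx] * log(p[idx]))
}

#' E-step of the Btm EM algorithm
#'
#' Computes the expected number of biterm endpoints assigned to each
#' signature: responsibilities `p(k|ij) = pi_k e_k(i) e_k(j) / P_ij`, then
#' `E[k, i] = sum_j (B_ij + B_ji) p(k|ij)` and `A[k] = sum_i E[k, i]`.
#' Because each biterm has two endpoints, `sum(A) == 2 * sum(B)`.
#'
#' @inheritParams btm_log_likelihood
#' @return List with `E` (K x M) and `A` (length K).
#' @export
btm_e_step <- function(model, b) {
  b <- as_biterm_matrix(b)
  check_model_dims(model, b)
  p <- btm_pair_probs(model$pi, model$e)
  w <- b + t(b)
  if (any(w > 0 & p <= 0)) {
    bad <- which(w > 0 & p <= 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "observed biterm (%d, %d) has zero probability under every signature",
      bad[1], bad[2]
    ))
  }
  g <- w / p
  g[w == 0] <- 0
  # E[k, i] = pi_k e_k(i) * sum_j G_ij e_k(j)
  e_stat <- (model$pi * model$e) * t(g %*% t(model$e))
  list(E = e_stat, A = rowSums(e_stat))
}

#' M-step of the Btm EM algorithm
#'
#' Normalizes the E-step statistics into new parameters:
#' `pi_k = A_k / sum(A)` and `e_k(i) = E[k, i] / sum_i E[k, i]`. A
#' signature with zero expected mass is reset to the uniform distribution
#' with epsilon exposure, then everything is renormalized; signature rows
#' are floored at `floor_eps` so no category ever has exactly zero
#' probability (held-out biterm matrices therefore always score finitely).
#'
#' @param E K x M matrix of expected endpoint counts.
#' @param A Length-K vector of expected signature totals.
#' @param floor_eps Lower bound applied to signature entries (default
#'   1e-12).
#' @return A `btm_model` with the updated parameters.
#' @export
btm_m_step <- function(E, A, floor_eps = 1e-12) {
  if (all(A <= 0)) abort("all signature totals are zero: no biterms to fit")
  pi <- A
  e <- E
  dead <- A <= 0
  if (any(dead)) {
    e[dead, ] <- 1 / ncol(E)
    pi[dead] <- .Machine$double.eps
  }
  e[!dead, ] <- e[!dead, , drop = FALSE] / rowSums(e[!dead, , drop = FALSE])
  e <- floor_rows(e, floor_eps)
  colnames(e) <- colnames(E)
  new_btm_model(pi = pi / sum(pi), e = e)
}

btm_random_init <- function(k, m, categories = NULL) {
  pi <- rdirichlet1(k, 1)
  e <- t(vapply(seq_len(k), function(i) rdirichlet1(m, 1), numeric(m)))
  e <- floor_rows(e)
  colnames(e) <- categories
  new_btm_model(pi = pi, e = e)
}

# Run `iters` EM iterations from a starting model; optionally record the
# per-iteration log-likelihood trace.
btm_em_run <- function(model, b, iters, trace = FALSE, floor_eps = 1e-12,
                       tol = NULL) {
  ll_trace <- if (trace) numeric(iters) else NULL
  w <- b + t(b)
  idx <- which(b > 0)
  bidx <- b[idx]
  ll <- NA_real_
  for (it in seq_len(iters)) {
    p <- btm_pair_probs(model$pi, model$e)
    g <- w / p
    g[w == 0] <- 0
    e_stat <- (model$pi * model$e) * t(g %*% t(model$e))
    new <- btm_m_step(e_stat, rowSums(e_stat), floor_eps)
    new$categories <- model$categories
    colnames(new$e) <- colnames(model$e)
    prev_ll <- ll
    ll <- sum(bidx * log(p[idx])) # LL of the model *entering* the iteration
    if (trace) ll_trace[it] <- ll
    model <- new
    if (!is.null(tol) && is.finite(prev_ll) &&
      abs(ll - prev_ll) <= tol * abs(prev_ll)) {
      if (trace) ll_trace <- ll_trace[seq_len(it)]
      break
    }
  }
  p <- btm_pair_probs(model$pi, model$e)
  model$train_ll <- sum(bidx * log(p[idx]))
  model$ll_trace <- if (trace) c(ll_trace, model$train_ll) else NULL
  model
}

#' Fit a biterm topic model by multi-seed EM
#'
#' Training follows a two-stage protocol: `n_seeds` independent random
#' initializations (exposures and signature rows drawn from symmetric
#' Dirichlet(1)) are each run for `burn_iters` EM iterations; the
#' initialization with the highest training log-likelihood (first
#' encountered wins ties) is then trained for `final_iters` further
#' iterations. With a fixed `seed` the result is bit-reproducible.
#'
#' @param b An M x M biterm matrix, or a catalog tibble (converted with
#'   [cohort_biterms()]).
#' @param k Number of signatures (>= 1).
#' @param n_seeds Number of random initializations (default 10).
#' @param burn_iters EM iterations per initialization (default 100).
#' @param final_iters Additional iterations for the best initialization
#'   (default 500).
#' @param seed Integer master seed; child seeds for the initializations are
#'   spawned from it deterministically.
#' @param trace If `TRUE`, store the final-stage log-likelihood trace in
#'   `$ll_trace`.
#' @param tol Optional relative change in log-likelihood below which EM
#'   stops early; `NULL` (default) runs the fixed iteration counts.
#' @param floor_eps Signature probability floor (default 1e-12).
#' @return A fitted `btm_model`.
#' @examples
#' b <- patient_biterms(c(5, 3, 2, 0))
#' fit <- train_btm(b, k = 1, seed = 1)
#' fit$pi
#' @export
train_btm <- function(b, k, n_seeds = 10, burn_iters = 100,
                      final_iters = 500, seed = 1, trace = FALSE,
                      tol = NULL, floor_eps = 1e-12) {
  stopifnot(k >= 1)
  b <- as_biterm_matrix(b)
  if (sum(b) == 0) abort("biterm matrix is empty: no co-occurring mutations")
  m <- ncol(b)
  active <- sum(colSums(b) + rowSums(b) > 0)
  if (k > active) {
    warn(sprintf(
      "k = %d exceeds the %d categories with positive biterm counts; extra signatures may collapse",
      k, active
    ))
  }
  seeds <- spawn_seeds(seed, n_seeds)
  best <- NULL
  for (s in seeds) {
    init <- with_rng(s, btm_random_init(k, m, colnames(b)))
    fit <- btm_em_run(init, b, burn_iters, trace = FALSE,
      floor_eps = floor_eps, tol = tol)
    if (is.null(best) || fit$train_ll > best$train_ll) best <- fit
  }
  out <- btm_em_run(best, b, final_iters, trace = trace,
    floor_eps = floor_eps, tol = tol)
  out$seed <- seed
  out$n_seeds <- n_seeds
  out$burn_iters <- burn_iters
  out$final_iters <- final_iters
  out$categories <- colnames(b)
  out
}

#' Extract a fitted model's signatures as a signature set
#'
#' @param model A fitted `btm_model` or `mix_model`.
#' @param prefix Name prefix for the learned signatures.
#' @return A signature set tibble (COSMIC layout).
#' @export
model_signatures <- function(model, prefix = "BtmSig") {
  e <- model$e
  cats <- model$categories %||% colnames(e) %||% paste0("cat", seq_len(ncol(e)))
  signature_set(e,
    signature_ids = paste0(prefix, seq_len(nrow(e))),
    categories = cats
  )
}
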