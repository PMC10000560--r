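# Btm2K: choose the number of signatures by repeated 2-fold
# cross-validation of Btm. Per repetition the non-big patients are split
# into two random halves; for each candidate K, Btm is trained on the
# biterms of one half plus all big patients and scored on the held-out
# half's biterm matrix, both ways, and the two held-out log-likelihoods
# are summed. The K with the best median score over repetitions is then
# rolled back to the smallest K whose scores are not significantly
# different (two-sided Wilcoxon rank-sum), preferring the more concise
# model when the evidence does not separate them.

new_btm2k_result <- function(scores, k_best, k_final, k_range, reps,
                             alpha, big_ids, folds, threshold) {
  structure(
    list(
      scores = scores, k_best = k_best, k_final = k_final,
      k_range = k_range, reps = reps, alpha = alpha,
      per_k_medians = scores |>
        dplyr::group_by(.data$k) |>
        dplyr::summarise(median_score = stats::median(.data$score)) |>
        tibble::deframe(),
      big_ids = big_ids, folds = folds, big_threshold = threshold
    ),
    class = "btm2k_result"
  )
}

#' @export
print.btm2k_result <- function(x, ...) {
  cat(sprintf(
    "Btm2K selection over K = %d..%d (%d repetitions)\n",
    x$k_range[1], x$k_range[2], x$reps
  ))
  cat(sprintf(
    "  best median K = %d, after rollback K = %d (alpha = %g)\n",
    x$k_best, x$k_final, x$alpha
  ))
  if (length(x$big_ids) > 0) {
    cat(sprintf(
      "  %d big patient(s) held in the training side of every fold\n",
      length(x$big_ids)
    ))
  }
  invisible(x)
}

#' Select the number of signatures by cross-validated Btm (Btm2K)
#'
#' Biterm counts grow quadratically with a sample's mutation burden, so a
#' handful of heavy samples ("big patients": more than `big_factor` times
#' the average biterm count) can dominate a fold and unbalance the
#' cross-validation. Big patients are therefore added to the training side
#' of both folds and never scored.
#'
#' @param catalog A catalog tibble.
#' @param k_min,k_max Candidate range of signature numbers
#'   (`1 <= k_min < k_max`).
#' @param reps Number of cross-validation repetitions (default 30).
#' @param big_factor Big-patient multiplier on the mean biterm count
#'   (default 5).
#' @param alpha Significance level of the rollback rank-sum test
#'   (default 0.05).
#' @param seed Master seed; splits and every Btm training run derive from
#'   it, so a fixed seed reproduces scores bit-for-bit.
#' @inheritParams train_btm
#' @return A `btm2k_result` holding the score table (tibble with columns
#'   `k`, `rep`, `score`), `k_best` (best median), `k_final` (after
#'   rollback), per-K medians, the big-patient ids, and the fold
#'   memberships of every repetition (for leakage audits).
#' @export
btm2k <- function(catalog, k_min = 1, k_max = 10, reps = 30, big_factor = 5,
                  alpha = 0.05, seed = 1, n_seeds = 10, burn_iters = 100,
                  final_iters = 500, tol = NULL) {
  stopifnot(k_min >= 1, k_min < k_max)
  parts <- split_big_patients(catalog, big_factor)
  rest <- parts$rest
  n_rest <- nrow(rest)
  if (n_rest < 4) abort("need at least 4 non-big patients for 2-fold CV")
  if (k_max >= n_rest) {
    abort(sprintf(
      "k_max = %d must be below the %d patients left after big-patient removal",
      k_max, n_rest
    ))
  }
  ks <- seq.int(k_min, k_max)
  b_big <- cohort_biterms(parts$big)
  rep_seeds <- spawn_seeds(seed, reps)
  rows <- vector("list", reps)
  folds <- vector("list", reps)
  for (t in seq_len(reps)) {
    split_seed <- rep_seeds[t]
    perm <- with_rng(split_seed, sample.int(n_rest))
    n1 <- ceiling(n_rest / 2) # odd count: extra sample to the first fold
    i1 <- sort(perm[seq_len(n1)])
    i2 <- sort(perm[-seq_len(n1)])
    b1 <- cohort_biterms(rest[i1, , drop = FALSE])
    b2 <- cohort_biterms(rest[i2, , drop = FALSE])
    train_seeds <- spawn_seeds(split_seed + 1L, 2L * length(ks))
    score_k <- numeric(length(ks))
    for (idx in seq_along(ks)) {
      fit1 <- train_btm(b1 + b_big, ks[idx],
        n_seeds = n_seeds, burn_iters = burn_iters,
        final_iters = final_iters, seed = train_seeds[2 * idx - 1], tol = tol
      )
      fit2 <- train_btm(b2 + b_big, ks[idx],
        n_seeds = n_seeds, burn_iters = burn_iters,
        final_iters = final_iters, seed = train_seeds[2 * idx], tol = tol
      )
      score_k[idx] <- btm_log_likelihood(fit1, b2) + btm_log_likelihood(fit2, b1)
    }
    rows[[t]] <- tibble::tibble(k = ks, rep = t, score = score_k)
    folds[[t]] <- list(
      fold1 = rest$sample_id[i1], fold2 = rest$sample_id[i2]
    )
  }
  scores <- dplyr::bind_rows(rows)
  med <- scores |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(m = stats::median(.data$score))
  k_best <- med$k[which.max(med$m)]
  k_final <- rollback(scores, k_best, alpha)
  new_btm2k_result(
    scores, k_best, k_final, c(k_min, k_max), reps, alpha,
    big_ids = parts$big$sample_id, folds = folds, threshold = parts$threshold
  )
}

#' Roll a selected hyper-parameter back toward parsimony
#'
#' Returns the smallest `k <= k_star` whose cross-validation scores are not
#' significantly different from `k_star`'s by a two-sided Wilcoxon rank-sum
#' test (normal approximation, mid-ranks for ties): the model is shrunk
#' whenever the evidence cannot separate it from the best-scoring one
#' (p > `alpha`). Smaller `alpha` makes fewer differences significant and
#' rolls back further; `alpha = 0` always returns the smallest candidate,
#' and `alpha` near 1 keeps `k_star` unless the score samples are
#' essentially identical.
#'
#' @param scores A tibble with columns `k`, `rep`, `score` (as in
#'   `btm2k()$scores`), or a `btm2k_result`.
#' @param k_star The best-scoring candidate to roll back from.
#' @param alpha Significance level (default 0.05).
#' @return The rolled-back integer `k <= k_star`.
#' @export
rollback <- function(scores, k_star, alpha = 0.05) {
  if (inherits(scores, "btm2k_result")) scores <- scores$scores
  stopifnot(all(c("k", "rep", "score") %in% names(scores)))
  ref <- scores$score[scores$k == k_star]
  if (length(ref) < 2) {
    warn("fewer than 2 repetitions: rollback skipped")
    return(k_star)
  }
  for (k in sort(unique(scores$k[scores$k < k_star]))) {
    p <- suppressWarnings(
      wilcox.test(scores$score[scores$k == k], ref,
        alternative = "two.sided", exact = FALSE, correct = TRUE
      )$p.value
    )
    if (is.na(p)) p <- 1 # identical constant samples: indistinguishable
    if (p > alpha) return(as.integer(k))
  }
  as.integer(k_star)
}

#' Select Mix hyper-parameters (K, L) by a BIC grid search
#'
#' Trains a Mix model at every (K, L) pair of the grid with the standard
#' multi-seed protocol and returns the pair minimizing the BIC.
#'
#' @param catalog A catalog tibble.
#' @param k_range,l_range Integer vectors of candidate signature and
#'   cluster numbers.
#' @param seed Master seed (one child seed per grid cell).
#' @param observations Passed to [mix_bic()].
#' @inheritParams train_mix
#' @return A list with the selected `k`, `l`, and `bic_table` (tibble with
#'   columns `k`, `l`, `bic`, `log_lik`).
#' @export
bic_grid_select <- function(catalog, k_range, l_range, seed = 1,
                            n_seeds = 10, burn_iters = 100, final_iters = 500,
                            tol = NULL, observations = "samples") {
  stopifnot(length(k_range) > 0, length(l_range) > 0)
  grid <- expand.grid(k = sort(unique(k_range)), l = sort(unique(l_range)))
  cell_seeds <- spawn_seeds(seed, nrow(grid))
  res <- purrr::pmap(
    list(grid$k, grid$l, cell_seeds),
    function(k, l, s) {
      fit <- train_mix(catalog, k = k, l = l,
        n_seeds = n_seeds, burn_iters = burn_iters,
        final_iters = final_iters, seed = s, tol = tol
      )
      tibble::tibble(
        k = k, l = l,
        bic = mix_bic(fit, catalog, observations = observations),
        log_lik = fit$train_ll
      )
    }
  )
  tab <- dplyr::bind_rows(res)
  best <- tab[which.min(tab$bic), ]
  list(k = best$k[[1]], l = best$l[[1]], bic_table = tab)
}

#' Select the number of Mix clusters for a fixed number of signatures
#'
#' One-dimensional slice of [bic_grid_select()].
#'
#' @inheritParams bic_grid_select
#' @param k The (fixed) number of signatures.
#' @return A list with the selected `l` and the `bic_table` slice.
#' @export
select_l_given_k <- function(catalog, k, l_range, seed = 1, ...) {
  out <- bic_grid_select(catalog, k_range = k, l_range = l_range,
    seed = seed, ...)
  list(l = out$l, bic_table = out$bic_table)
}
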