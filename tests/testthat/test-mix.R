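make_mix <- function(w, pi, e) {
  structure(list(w = w, pi = as.matrix(pi), e = e, l = length(w),
    k = nrow(e), categories = NULL), class = "mix_model")
}

test_that("likelihood closed forms: single component and collapsed mixture", {
  # L=1, K=1: plain multinomial log-likelihood (no coefficient)
  e <- matrix(c(0.2, 0.3, 0.5), 1, 3)
  m1 <- make_mix(1, matrix(1, 1, 1), e)
  v <- rbind(c(2, 0, 1), c(0, 3, 0))
  expect_equal(mix_log_likelihood(m1, v), sum(v %*% log(t(e))))

  # identical clusters collapse to the L=1 value
  m2 <- make_mix(c(0.3, 0.7), matrix(1, 2, 1), e)
  expect_equal(mix_log_likelihood(m2, v), mix_log_likelihood(m1, v))

  # positive count on an impossible category
  e0 <- matrix(c(1, 0, 0), 1, 3)
  expect_equal(mix_log_likelihood(make_mix(1, matrix(1, 1, 1), e0), v), -Inf)
})

test_that("likelihood matches direct evaluation of the product-sum", {
  withr::local_seed(41)
  for (rep in 1:30) {
    n <- sample(1:3, 1); m <- sample(2:4, 1)
    l <- sample(1:2, 1); k <- sample(1:2, 1)
    v <- matrix(rpois(n * m, 2), n, m)
    w <- random_simplex(l)
    pi <- matrix(unlist(lapply(seq_len(l), function(i) random_simplex(k))),
      nrow = l, byrow = TRUE)
    e <- matrix(unlist(lapply(seq_len(k), function(i) random_simplex(m))),
      nrow = k, byrow = TRUE)
    expect_equal(
      mix_log_likelihood(make_mix(w, pi, e), v),
      oracle_mix_loglik(w, pi, e, v),
      tolerance = 1e-10
    )
  }
})

test_that("L=1, K=1 training yields the pooled empirical distribution", {
  withr::local_seed(42)
  v <- matrix(rpois(5 * 4, 3), 5, 4)
  fit <- train_mix(toy_catalog(v), k = 1, l = 1, n_seeds = 2,
    burn_iters = 20, final_iters = 30, seed = 1)
  expect_equal(fit$w, 1)
  expect_equal(unname(fit$pi), matrix(1, 1, 1))
  expect_equal(unname(fit$e[1, ]), colSums(v) / sum(v), tolerance = 1e-9)
})

test_that("with L=1 the EM fixed point matches a direct multinomial-mixture fit", {
  # single-cluster Mix is a plain mixture of multinomials: run a naive MMM
  # EM (independent implementation) from the same start and compare a step
  withr::local_seed(43)
  v <- matrix(rpois(6 * 5, 3), 6, 5)
  k <- 2
  pi0 <- random_simplex(k)
  e0 <- t(vapply(1:k, function(i) random_simplex(5), numeric(5)))
  model <- make_mix(1, matrix(pi0, 1, k), e0)

  naive_step <- function(pi, e, v) {
    # responsibilities per mutation category under pooled counts
    pooled <- colSums(v)
    q <- vapply(seq_len(ncol(v)), function(j) {
      r <- pi * e[, j]
      r / sum(r)
    }, numeric(k)) # K x M
    nk <- q * rep(pooled, each = k)
    pi_new <- rowSums(nk) / sum(nk)
    e_new <- nk / rowSums(nk)
    list(pi = pi_new, e = e_new)
  }
  stepped <- btmsig:::mix_em_iterate(model, v)
  want <- naive_step(pi0, e0, v)
  expect_equal(unname(stepped$pi[1, ]), want$pi, tolerance = 1e-10)
  expect_equal(unname(stepped$e), unname(want$e), tolerance = 1e-10)
})

test_that("training log-likelihood is monotone and reproducible", {
  withr::local_seed(44)
  cat1 <- random_sbs_catalog(25, mean_burden = 15)
  fit <- train_mix(cat1, k = 2, l = 2, n_seeds = 2, burn_iters = 30,
    final_iters = 60, seed = 3, trace = TRUE)
  tr <- fit$ll_trace
  expect_true(all(diff(tr) >= -1e-9 * abs(tr[-length(tr)])))
  fit2 <- train_mix(cat1, k = 2, l = 2, n_seeds = 2, burn_iters = 30,
    final_iters = 60, seed = 3, trace = TRUE)
  expect_identical(fit$e, fit2$e)
  expect_identical(fit$pi, fit2$pi)
  expect_identical(fit$w, fit2$w)
  expect_error(train_mix(cat1, k = 2, l = 100, seed = 1), "exceeds")
})

test_that("fixed-signature refit leaves e untouched and still improves LL", {
  withr::local_seed(45)
  sigs <- random_signatures(2, m = 96, seed = 51)
  truth <- simulation_truth(sigs, cluster_weights = c(0.5, 0.5),
    cluster_exposures = rbind(c(0.9, 0.1), c(0.1, 0.9)))
  sim <- sample_catalog(truth, 60, burden = burden_fixed(30), seed = 52)
  fit <- train_mix(sim$catalog, k = 2, l = 2, n_seeds = 2, burn_iters = 20,
    final_iters = 40, seed = 53, fixed_signatures = sigs)
  floored <- btmsig:::floor_rows(signature_matrix(sigs), 1e-12)
  expect_equal(unname(fit$e), unname(floored), tolerance = 0)
  expect_true(is.finite(fit$train_ll))
})

test_that("BIC uses p = (L-1) + L(K-1) + K(M-1) and can prefer the smaller model", {
  expect_equal(btmsig:::mix_n_parameters(5, 7, 96), 699)
  expect_equal(btmsig:::mix_n_parameters(1, 1, 2), 1)

  # closed form at L=1, K=1, M=2, N=10
  withr::local_seed(46)
  v <- matrix(rpois(10 * 2, 4) + 1, 10, 2)
  fit <- train_mix(toy_catalog(v), k = 1, l = 1, n_seeds = 1,
    burn_iters = 5, final_iters = 5, seed = 1)
  expect_equal(mix_bic(fit, toy_catalog(v)),
    log(10) - 2 * fit$train_ll, tolerance = 1e-9)

  # nested models: larger has LL >= smaller (same data), BIC may not
  withr::local_seed(47)
  cat1 <- random_sbs_catalog(15, mean_burden = 20)
  small <- train_mix(cat1, k = 1, l = 1, n_seeds = 2, burn_iters = 20,
    final_iters = 40, seed = 2)
  large <- train_mix(cat1, k = 2, l = 2, n_seeds = 4, burn_iters = 20,
    final_iters = 40, seed = 2)
  expect_gte(large$train_ll, small$train_ll - 1e-6 * abs(small$train_ll))
  # mutation-count observation switch changes only the penalty scale
  expect_equal(
    mix_bic(small, cat1, observations = "mutations") + 2 * small$train_ll,
    btmsig:::mix_n_parameters(1, 1, 96) * log(sum(catalog_matrix(cat1)))
  )
})

test_that("held-out likelihood is the training formula on unseen samples", {
  withr::local_seed(48)
  cat1 <- random_sbs_catalog(12, mean_burden = 10)
  fit <- train_mix(cat1, k = 2, l = 2, n_seeds = 2, burn_iters = 10,
    final_iters = 20, seed = 4)
  expect_equal(mix_heldout_log_likelihood(fit, cat1), fit$train_ll,
    tolerance = 1e-9)
  # empty catalog scores zero; random held-out split stays finite
  empty <- cat1[0, ]
  expect_equal(mix_heldout_log_likelihood(fit, empty), 0)
  other <- random_sbs_catalog(6, mean_burden = 10)
  expect_true(is.finite(mix_heldout_log_likelihood(fit, other)))
})

test_that("cluster responsibilities recover well-separated clusters", {
  sigs <- random_signatures(3, m = 96, concentration = 0.1, seed = 61)
  truth <- simulation_truth(sigs,
    cluster_weights = c(0.5, 0.5),
    cluster_exposures = rbind(c(0.85, 0.1, 0.05), c(0.05, 0.1, 0.85))
  )
  sim <- sample_catalog(truth, 200, burden = burden_fixed(50), seed = 62)
  fit <- train_mix(sim$catalog, k = 3, l = 2, n_seeds = 4, burn_iters = 30,
    final_iters = 100, seed = 63)
  resp <- mix_responsibilities(fit, sim$catalog)
  acc <- label_match_accuracy(sim$sample_cluster, resp$cluster, 2)
  expect_gte(acc, 0.95)
  # recovered cluster weights near truth
  expect_true(all(abs(sort(fit$w) - c(0.5, 0.5)) < 0.1))
})

test_that("signatures are recovered when clusters identify them (L = K)", {
  # the likelihood sees only the L cluster-level category mixtures, so
  # individual signatures are identifiable only through exposure contrast
  # across clusters; with one dominant signature per cluster the learned
  # signatures must approach the truth
  sigs <- random_signatures(3, m = 96, concentration = 0.1, seed = 64)
  truth <- simulation_truth(sigs,
    cluster_weights = c(0.4, 0.35, 0.25),
    cluster_exposures = rbind(c(0.9, 0.05, 0.05), c(0.05, 0.9, 0.05),
      c(0.05, 0.05, 0.9))
  )
  sim <- sample_catalog(truth, 300, burden = burden_fixed(80), seed = 65)
  fit <- train_mix(sim$catalog, k = 3, l = 3, n_seeds = 6, burn_iters = 50,
    final_iters = 200, seed = 66)
  tv <- matched_tv(fit$e, signature_matrix(sigs))
  expect_true(all(tv < 0.1))
})
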