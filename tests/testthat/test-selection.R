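score_table <- function(by_k) {
  # by_k: named list k -> numeric vector of repetition scores
  dplyr::bind_rows(lapply(names(by_k), function(kk) {
    tibble::tibble(k = as.integer(kk), rep = seq_along(by_k[[kk]]),
      score = by_k[[kk]])
  }))
}

test_that("rollback returns the smallest statistically indistinguishable K", {
  withr::local_seed(51)
  base <- rnorm(10)
  # identical score vectors for every K: rolls all the way to k_min
  tab <- score_table(list(`1` = base, `2` = base, `3` = base, `4` = base))
  expect_equal(rollback(tab, 4), 1L)

  # fully separated score samples: no rollback
  tab2 <- score_table(list(`1` = base - 1000, `2` = base - 500, `3` = base))
  expect_equal(rollback(tab2, 3), 3L)

  # middle K indistinguishable, smaller K clearly worse
  tab3 <- score_table(list(`1` = base - 1000, `2` = base + rnorm(10, 0, 0.1),
    `3` = base))
  expect_equal(rollback(tab3, 3), 2L)
})

test_that("rollback is monotone in alpha with full-rollback and no-rollback limits", {
  withr::local_seed(52)
  base <- rnorm(10)
  tab <- score_table(list(
    `1` = base - 50, `2` = base - 2, `3` = base - 0.5, `4` = base
  ))
  # alpha = 0: nothing is significant, everything rolls back
  expect_equal(rollback(tab, 4, alpha = 0), 1L)
  # alpha near 1: every difference is significant, k_star kept
  expect_equal(rollback(tab, 4, alpha = 0.9999), 4L)
  alphas <- c(0, 1e-6, 1e-3, 0.05, 0.5, 0.9999)
  ks <- vapply(alphas, function(a) rollback(tab, 4, alpha = a), 0L)
  expect_true(all(diff(ks) >= 0))
  expect_true(all(ks <= 4))
})

test_that("rollback warns and keeps k_star with a single repetition", {
  tab <- score_table(list(`1` = 1, `2` = 2))
  expect_warning(out <- rollback(tab, 2), "repetitions")
  expect_equal(out, 2L)
})

test_that("btm2k picks the dominating K on a degenerate two-point range", {
  # co-occurrence signal comes from exposure heterogeneity across samples:
  # three clusters, each dominated by one signature
  sigs <- random_signatures(3, m = 96, concentration = 0.1, seed = 71)
  truth <- simulation_truth(sigs,
    cluster_weights = c(0.5, 0.3, 0.2),
    cluster_exposures = rbind(c(0.8, 0.1, 0.1), c(0.1, 0.8, 0.1),
      c(0.1, 0.1, 0.8)))
  sim <- sample_catalog(truth, 200, burden = burden_fixed(25), seed = 72)
  res <- btm2k(sim$catalog, k_min = 1, k_max = 2, reps = 4,
    seed = 73, n_seeds = 3, burn_iters = 30, final_iters = 60)
  # 3 generating signatures: K=2 dominates K=1 on every repetition
  by_k <- split(res$scores$score, res$scores$k)
  expect_true(all(by_k[["2"]] > by_k[["1"]]))
  expect_equal(res$k_best, 2L)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(glance(res)$k_final, res$k_final)
})

test_that("btm2k holds big patients out of every test fold and is reproducible", {
  sigs <- random_signatures(2, m = 96, seed = 81)
  truth <- simulation_truth(sigs, cluster_exposures = matrix(c(0.6, 0.4), 1))
  sim <- sample_catalog(truth, 40, burden = burden_fixed(12), seed = 82)
  cat1 <- sim$catalog
  # implant two unmistakably big patients
  m <- catalog_matrix(cat1)
  m[1, ] <- m[1, ] + 60L
  m[2, ] <- m[2, ] + 80L
  cat1 <- mutation_catalog(m)
  parts <- split_big_patients(cat1)
  expect_setequal(parts$big$sample_id, cat1$sample_id[1:2])

  res <- btm2k(cat1, k_min = 1, k_max = 2, reps = 3, seed = 5,
    n_seeds = 2, burn_iters = 10, final_iters = 20)
  expect_equal(res$big_ids, cat1$sample_id[1:2])
  for (f in res$folds) {
    expect_length(intersect(res$big_ids, f$fold1), 0)
    expect_length(intersect(res$big_ids, f$fold2), 0)
    # folds partition the non-big patients, extra sample to fold 1
    expect_setequal(c(f$fold1, f$fold2), parts$rest$sample_id)
    expect_gte(length(f$fold1), length(f$fold2))
  }
  expect_lte(res$k_final, res$k_best)

  res2 <- btm2k(cat1, k_min = 1, k_max = 2, reps = 3, seed = 5,
    n_seeds = 2, burn_iters = 10, final_iters = 20)
  expect_identical(res$scores, res2$scores)
  expect_identical(res$folds, res2$folds)

  expect_error(btm2k(cat1, k_min = 1, k_max = 50, reps = 2, seed = 1), "k_max")
})

test_that("BIC grid search returns the minimizing cell and its table", {
  withr::local_seed(53)
  sigs <- random_signatures(1, m = 96, seed = 91)
  truth <- simulation_truth(sigs)
  sim <- sample_catalog(truth, 50, burden = burden_fixed(30), seed = 92)
  single <- bic_grid_select(sim$catalog, k_range = 2, l_range = 2, seed = 1,
    n_seeds = 1, burn_iters = 5, final_iters = 5)
  expect_equal(single$k, 2)
  expect_equal(single$l, 2)
  expect_equal(nrow(single$bic_table), 1)

  grid <- bic_grid_select(sim$catalog, k_range = 1:2, l_range = 1:2,
    seed = 2, n_seeds = 2, burn_iters = 15, final_iters = 30)
  expect_equal(nrow(grid$bic_table), 4)
  best_row <- grid$bic_table[which.min(grid$bic_table$bic), ]
  expect_equal(grid$k, best_row$k[[1]])
  expect_equal(grid$l, best_row$l[[1]])

  slice <- select_l_given_k(sim$catalog, k = 1, l_range = 1:2, seed = 3,
    n_seeds = 2, burn_iters = 15, final_iters = 30)
  expect_equal(slice$l,
    slice$bic_table$l[which.min(slice$bic_table$bic)][[1]])
})

test_that("strong 2-cluster structure selects L = 2 given the true K", {
  sigs <- random_signatures(2, m = 96, concentration = 0.1, seed = 95)
  truth <- simulation_truth(sigs,
    cluster_weights = c(0.5, 0.5),
    cluster_exposures = rbind(c(0.95, 0.05), c(0.05, 0.95))
  )
  sim <- sample_catalog(truth, 120, burden = burden_fixed(40), seed = 96)
  slice <- select_l_given_k(sim$catalog, k = 2, l_range = 1:3, seed = 97,
    n_seeds = 3, burn_iters = 25, final_iters = 60)
  expect_equal(slice$l, 2)
})
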