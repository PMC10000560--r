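# Synthetic catalog and biterm generators. These emulate the statistical
# structure the models assume -- per-sample multinomial draws from mixtures
# of signatures, cluster structure over samples, heavy-tailed mutation
# burdens producing "big patients", and panel-level binomial thinning --
# so the full pipeline is exercisable without external data.

#' Ground truth for a simulated cohort
#'
#' Bundles the generating signatures, cluster structure, and seed of a
#' simulation so downstream evaluation can score recovered parameters
#' against the truth.
#'
#' @param signatures A signature set tibble (K signatures).
#' @param cluster_weights Length-L prior over clusters (default one
#'   cluster).
#' @param cluster_exposures L x K matrix of per-cluster exposures, rows
#'   summing to 1 (default uniform).
#' @param seed Integer seed recorded with the truth.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(signatures, cluster_weights = 1,
                             cluster_exposures = NULL, seed = NULL) {
  e <- signature_matrix(signatures)
  k <- nrow(e)
  l <- length(cluster_weights)
  if (is.null(cluster_exposures)) {
    cluster_exposures <- matrix(1 / k, l, k)
  }
  cluster_exposures <- as.matrix(cluster_exposures)
  stopifnot(
    nrow(cluster_exposures) == l, ncol(cluster_exposures) == k,
    abs(sum(cluster_weights) - 1) < 1e-9,
    all(abs(rowSums(cluster_exposures) - 1) < 1e-9)
  )
  structure(
    list(
      signatures = signatures, e = e,
      cluster_weights = as.numeric(cluster_weights),
      cluster_exposures = cluster_exposures,
      k = k, l = l, seed = seed
    ),
    class = "simulation_truth"
  )
}

#' Random well-separated signatures
#'
#' Draws K sparse signatures from a symmetric Dirichlet and redraws until
#' every pairwise cosine similarity is below `max_cosine`, giving
#' well-separated mutational processes for recovery experiments.
#'
#' @param k Number of signatures.
#' @param m Number of categories (96 by default; labels are the canonical
#'   SBS-96 set when `m == 96`, `"cat1"..."catM"` otherwise).
#' @param concentration Dirichlet concentration (small values give sparse,
#'   peaky signatures; default 0.1).
#' @param max_cosine Maximum allowed pairwise cosine (default 0.3).
#' @param seed Integer seed.
#' @return A signature set tibble.
#' @export
random_signatures <- function(k, m = 96, concentration = 0.1,
                              max_cosine = 0.3, seed = 1) {
  cats <- if (m == 96) sbs96_categories() else sprintf("cat%03d", seq_len(m))
  with_rng(seed, {
    for (attempt in seq_len(200)) {
      e <- t(vapply(seq_len(k), function(i) rdirichlet1(m, concentration),
        numeric(m)))
      if (k == 1 || max(cosine_matrix(e, e)[upper.tri(diag(k))]) < max_cosine) {
        return(signature_set(e,
          signature_ids = paste0("TrueSig", seq_len(k)), categories = cats
        ))
      }
    }
    abort("could not draw signatures this well separated; raise max_cosine or lower concentration")
  })
}

#' Sample a biterm matrix from a Btm generative model
#'
#' Each draw picks a signature `z` from `pi`, then two categories `i`, `j`
#' independently from signature `z`; both orientations `(i, j)` and
#' `(j, i)` are incremented, so the matrix is symmetric and totals
#' `2 * n_biterms`.
#'
#' @param pi Length-K probability vector of global exposures.
#' @param e K x M signature matrix (rows sum to 1) or a signature set
#'   tibble.
#' @param n_biterms Number of biterm draws (>= 0).
#' @param seed Integer seed.
#' @return An M x M symmetric count matrix.
#' @export
sample_biterms <- function(pi, e, n_biterms, seed = 1) {
  if (is.data.frame(e)) e <- signature_matrix(e)
  e <- as.matrix(e)
  stopifnot(abs(sum(pi) - 1) < 1e-9, all(abs(rowSums(e) - 1) < 1e-9))
  if (n_biterms < 0) abort("n_biterms must be non-negative")
  m <- ncol(e)
  b <- matrix(0, m, m, dimnames = list(colnames(e), colnames(e)))
  if (n_biterms == 0) return(b)
  with_rng(seed, {
    z <- sample.int(length(pi), n_biterms, replace = TRUE, prob = pi)
    i <- integer(n_biterms)
    j <- integer(n_biterms)
    for (k in unique(z)) {
      sel <- which(z == k)
      i[sel] <- sample.int(m, length(sel), replace = TRUE, prob = e[k, ])
      j[sel] <- sample.int(m, length(sel), replace = TRUE, prob = e[k, ])
    }
    tab <- table(factor(i, levels = seq_len(m)), factor(j, levels = seq_len(m)))
    draws <- matrix(as.numeric(tab), m, m)
    b <- b + draws + t(draws)
  })
  b
}

#' Burden distributions for simulated catalogs
#'
#' `burden_fixed(s)` gives every sample exactly `s` mutations.
#' `burden_lognormal(mean, sigma)` draws log-normal burdens with the given
#' arithmetic mean and log-scale standard deviation `sigma`, rounded to
#' integers -- the heavy right tail produces the occasional very heavy
#' sample ("big patient") seen in real cohorts.
#'
#' @param s Fixed per-sample mutation count.
#' @return A burden specification consumed by [sample_catalog()].
#' @export
burden_fixed <- function(s) {
  stopifnot(s >= 0, s == round(s))
  structure(list(type = "fixed", s = s), class = "burden_spec")
}

#' @rdname burden_fixed
#' @param mean Arithmetic mean of the burden distribution.
#' @param sigma Log-scale standard deviation (default 1.4).
#' @export
burden_lognormal <- function(mean, sigma = 1.4) {
  stopifnot(mean > 0, sigma >= 0)
  structure(list(type = "lognormal", mean = mean, sigma = sigma),
    class = "burden_spec")
}

draw_burdens <- function(spec, n) {
  if (!inherits(spec, "burden_spec")) {
    if (is.numeric(spec) && length(spec) == 1) spec <- burden_fixed(spec)
    else abort("burden must be a burden_spec or a single fixed count")
  }
  switch(spec$type,
    fixed = rep(spec$s, n),
    lognormal = {
      mu <- log(spec$mean) - spec$sigma^2 / 2 # arithmetic mean = `mean`
      pmax(0L, as.integer(round(rlnorm(n, mu, spec$sigma))))
    }
  )
}

#' Sample a mutation catalog from a simulation truth
#'
#' Per sample: a cluster is drawn from the truth's cluster weights, a total
#' mutation burden from `burden`, and that many categories i.i.d. from the
#' cluster's mixture distribution over categories.
#'
#' @param truth A [simulation_truth()].
#' @param n_samples Number of samples to draw.
#' @param burden A burden spec ([burden_fixed()], [burden_lognormal()]) or
#'   a single fixed count.
#' @param seed Integer seed.
#' @return A list of class `simulated_catalog`: `catalog` (tibble),
#'   `sample_cluster` (length-N integers), `sample_exposures` (N x K, row
#'   `n` is the exposure row of sample `n`'s cluster), and `truth`.
#' @export
sample_catalog <- function(truth, n_samples, burden = burden_fixed(7),
                           seed = 1) {
  stopifnot(inherits(truth, "simulation_truth"), n_samples >= 0)
  m <- ncol(truth$e)
  cats <- colnames(truth$e)
  pcat <- truth$cluster_exposures %*% truth$e # L x M cluster mixtures
  with_rng(seed, {
    cl <- sample.int(truth$l, n_samples,
      replace = TRUE, prob = truth$cluster_weights
    )
    s <- draw_burdens(burden, n_samples)
    counts <- matrix(0L, n_samples, m)
    for (n in seq_len(n_samples)) {
      if (s[n] == 0) next
      counts[n, ] <- as.integer(stats::rmultinom(1, s[n], pcat[cl[n], ]))
    }
    colnames(counts) <- cats
    catalog <- mutation_catalog(counts,
      sample_ids = sprintf("sim%04d", seq_len(n_samples)), categories = cats
    )
    structure(
      list(
        catalog = catalog,
        sample_cluster = cl,
        sample_exposures = truth$cluster_exposures[cl, , drop = FALSE],
        truth = truth,
        seed = seed
      ),
      class = "simulated_catalog"
    )
  })
}

#' Thin a catalog to panel depth
#'
#' Models targeted-panel capture as binomial thinning: each mutation is
#' retained independently with probability `keep_prob` (per-cell binomial
#' draws). The sample set is unchanged. `keep_prob` may be a single number
#' or a per-category vector to mimic panel composition bias.
#'
#' @param catalog A catalog tibble.
#' @param keep_prob Retention probability in `[0, 1]` (scalar or length-M).
#' @param seed Integer seed.
#' @return A catalog tibble of the same shape with thinned counts.
#' @export
downsample_catalog <- function(catalog, keep_prob, seed = 1) {
  v <- catalog_matrix(catalog)
  if (any(keep_prob < 0) || any(keep_prob > 1)) {
    abort("keep_prob must lie in [0, 1]")
  }
  if (length(keep_prob) == 1) keep_prob <- rep(keep_prob, ncol(v))
  stopifnot(length(keep_prob) == ncol(v))
  kept <- with_rng(seed, {
    out <- v
    for (j in seq_len(ncol(v))) {
      out[, j] <- rbinom(nrow(v), size = v[, j], prob = keep_prob[j])
    }
    out
  })
  mutation_catalog(kept,
    sample_ids = catalog$sample_id, categories = colnames(v)
  )
}

#' Named synthetic regimes
#'
#' `"panel-like"` emulates a large targeted-sequencing cohort: 5000
#' samples with a heavy-tailed burden averaging about 7 mutations per
#' sample. `"wgs-like"` emulates a rich cohort: 300 samples with burdens
#' in the thousands.
#'
#' @param preset `"panel-like"` or `"wgs-like"`.
#' @param k Number of generating signatures (default 3).
#' @param l Number of sample clusters (default 1).
#' @param n_samples Override the preset's cohort size.
#' @param seed Integer seed driving signatures, truth, and draws.
#' @return A `simulated_catalog` (see [sample_catalog()]).
#' @export
simulate_preset <- function(preset = c("panel-like", "wgs-like"), k = 3,
                            l = 1, n_samples = NULL, seed = 1) {
  preset <- match.arg(preset)
  seeds <- spawn_seeds(seed, 4)
  sigs <- random_signatures(k, 96, seed = seeds[1])
  weights <- if (l == 1) 1 else with_rng(seeds[2], rdirichlet1(l, 5))
  expos <- with_rng(
    seeds[3],
    t(vapply(seq_len(l), function(i) rdirichlet1(k, 2), numeric(k)))
  )
  if (k == 1) expos <- matrix(1, l, 1)
  truth <- simulation_truth(sigs,
    cluster_weights = weights,
    cluster_exposures = expos, seed = seed
  )
  if (preset == "panel-like") {
    n <- n_samples %||% 5000
    burden <- burden_lognormal(mean = 7, sigma = 1.4)
  } else {
    n <- n_samples %||% 300
    burden <- burden_lognormal(mean = 3000, sigma = 1.4)
  }
  sample_catalog(truth, n, burden = burden, seed = seeds[4])
}
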