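# Internal numerical helpers shared across the models.

# Draw one Dirichlet(alpha) vector of length n via normalized gammas.
rdirichlet1 <- function(n, alpha = 1) {
  x <- rgamma(n, shape = alpha, rate = 1)
  # guard against all-zero draws at tiny alpha
  if (sum(x) <= 0) x <- rep(1, n)
  x / sum(x)
}

# Run code under a temporary RNG state seeded with `seed`; restores the
# caller's RNG so library calls never perturb user-level reproducibility.
with_rng <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Deterministic child seeds spawned from a master seed, so a multi-seed
# training run is reproducible as a unit. Kept below 2^31 - 1.
spawn_seeds <- function(seed, n) {
  with_rng(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Row-wise log-sum-exp of a matrix.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

# Cosine similarity between two non-negative vectors.
#' Cosine similarity between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single number in `[-1, 1]` (in `[0, 1]` for non-negative input).
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    abort("cosine similarity undefined for a zero vector")
  }
  sum(x * y) / (nx * ny)
}

#' Total-variation distance between two discrete distributions
#'
#' @param p,q Probability vectors of equal length.
#' @return `0.5 * sum(|p - q|)`, in `[0, 1]`.
#' @export
total_variation <- function(p, q) {
  0.5 * sum(abs(p - q))
}

# Floor a probability matrix row-wise at `eps` and renormalize each row.
floor_rows <- function(x, eps = 1e-12) {
  x[x < eps] <- eps
  x / rowSums(x)
}

floor_vec <- function(x, eps = 1e-12) {
  x[x < eps] <- eps
  x / sum(x)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
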