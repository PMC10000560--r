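# Biterms: ordered pairs of distinct mutation instances co-occurring in a
# patient. For a patient with count vector V the biterm matrix is
# B = V^T V - diag(V); the cohort matrix sums these over patients. The
# diagonal is retained (B[i,i] = V_i (V_i - 1)) and off-diagonal pairs are
# counted in both orientations, so a patient with S mutations contributes
# S(S-1) biterms in total.

#' Biterm matrix of a single patient
#'
#' @param counts Length-M vector of non-negative integer category counts.
#' @return An M x M symmetric integer matrix `outer(counts, counts) -
#'   diag(counts)`.
#' @examples
#' patient_biterms(c(2, 1))
#' @export
patient_biterms <- function(counts) {
  counts <- as.numeric(counts)
  if (!is_count_vector(counts)) {
    abort("counts must be non-negative integers")
  }
  b <- outer(counts, counts)
  diag(b) <- diag(b) - counts
  b
}

#' Aggregate biterm matrix of a cohort
#'
#' Sums the per-patient biterm matrices over all samples of a catalog. For
#' catalogs with few total mutations relative to `N * M^2` the same result
#' is accumulated patient-by-patient over the nonzero categories only;
#' otherwise one dense cross-product is used. Both routes are exact.
#'
#' @param catalog A catalog tibble, or a numeric count matrix (samples in
#'   rows).
#' @return An M x M symmetric matrix of biterm counts with category
#'   dimnames.
#' @export
cohort_biterms <- function(catalog) {
  v <- if (is.data.frame(catalog)) catalog_matrix(catalog) else {
    m <- as.matrix(catalog)
    validate_counts(m)
    m
  }
  if (nrow(v) == 0) {
    b <- matrix(0, ncol(v), ncol(v))
  } else if (sum(rowSums(v)^2) < nrow(v) * ncol(v)^2 / 8) {
    # sparse route: per-patient outer products over nonzero categories
    b <- matrix(0, ncol(v), ncol(v))
    for (n in seq_len(nrow(v))) {
      nz <- which(v[n, ] > 0)
      if (length(nz) == 0) next
      vn <- v[n, nz]
      b[nz, nz] <- b[nz, nz] + outer(vn, vn)
      b[cbind(nz, nz)] <- b[cbind(nz, nz)] - vn
    }
  } else {
    b <- crossprod(v)
    diag(b) <- diag(b) - colSums(v)
  }
  dimnames(b) <- list(colnames(v), colnames(v))
  b
}

#' Total number of biterms per patient
#'
#' A patient with `S` mutations holds `S * (S - 1)` ordered biterms (the
#' total of its biterm matrix, diagonal included).
#'
#' @param catalog A catalog tibble or count matrix.
#' @return Numeric vector, one entry per sample.
#' @export
patient_biterm_totals <- function(catalog) {
  v <- if (is.data.frame(catalog)) catalog_matrix(catalog) else as.matrix(catalog)
  s <- rowSums(v)
  setNames(s * (s - 1), rownames(v))
}

#' Partition a catalog into big patients and the rest
#'
#' Big patients are samples whose biterm count exceeds `factor` times the
#' cohort-average biterm count. Because biterms grow quadratically with the
#' mutation burden, a few heavy samples can hold most of the biterms;
#' cross-validated model selection keeps them in the training side of every
#' fold.
#'
#' @param catalog A catalog tibble.
#' @param factor Positive multiplier on the mean biterm count (default 5).
#' @return A list with catalog tibbles `big` and `rest` (sample order
#'   preserved within each) and the numeric `threshold` used.
#' @export
split_big_patients <- function(catalog, factor = 5) {
  stopifnot(is.numeric(factor), factor > 0)
  tot <- patient_biterm_totals(catalog)
  if (length(tot) == 0) abort("catalog has no samples")
  thr <- big_patient_threshold(tot, factor)
  is_big <- tot > thr
  list(
    big = catalog[is_big, , drop = FALSE],
    rest = catalog[!is_big, , drop = FALSE],
    threshold = thr
  )
}

big_patient_threshold <- function(biterm_totals, factor = 5) {
  factor * mean(biterm_totals)
}

#' Biterm matrix as a tidy tibble
#'
#' @param b An M x M biterm matrix.
#' @return Tibble with columns `category_i`, `category_j`, `n`.
#' @export
tidy_biterms <- function(b) {
  cats <- colnames(b) %||% as.character(seq_len(ncol(b)))
  tibble::tibble(
    category_i = rep(cats, times = ncol(b)),
    category_j = rep(cats, each = nrow(b)),
    n = as.vector(b)
  )
}
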