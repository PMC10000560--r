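#' Build a mutation catalog tibble
#'
#' A mutation catalog is a tibble with one row per sample: a `sample_id`
#' column followed by one integer count column per mutation category, in
#' canonical order (see [sbs96_categories()]). All user-facing functions in
#' the package accept and return catalogs in this layout so pipelines
#' compose with the pipe.
#'
#' @param counts Numeric matrix, samples in rows, categories in columns
#'   (non-negative integers). Column names, if present, must match
#'   `categories`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to the matrix rownames or `"S1"..."SN"`.
#' @param categories Character vector of category labels; defaults to the
#'   canonical SBS-96 set. Input columns are reordered to the canonical
#'   order of this set.
#' @return A tibble with `N` rows and `1 + M` columns.
#' @examples
#' cat96 <- mutation_catalog(matrix(1L, 2, 96))
#' dim(cat96)
#' @export
mutation_catalog <- function(counts, sample_ids = NULL,
                             categories = sbs96_categories()) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(counts) %||% paste0("S", seq_len(nrow(counts)))
  }
  if (anyDuplicated(sample_ids)) {
    abort("sample_ids must be unique")
  }
  if (!is.null(colnames(counts))) {
    check_categories(colnames(counts), categories)
    counts <- counts[, categories, drop = FALSE]
  } else if (ncol(counts) != length(categories)) {
    abort(sprintf(
      "counts has %d columns but %d categories were given",
      ncol(counts), length(categories)
    ))
  }
  validate_counts(counts)
  out <- tibble::as_tibble(as.data.frame(counts, optional = TRUE),
    .name_repair = "minimal"
  )
  names(out) <- categories
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), as.integer))
  dplyr::bind_cols(tibble::tibble(sample_id = as.character(sample_ids)), out)
}

validate_counts <- function(counts) {
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
    arr.ind = TRUE
  )
  if (nrow(bad) > 0) {
    abort(sprintf(
      "counts must be non-negative integers; offending cell at row %d, column %d (value %s)",
      bad[1, 1], bad[1, 2], format(counts[bad[1, 1], bad[1, 2]])
    ))
  }
  invisible(counts)
}

#' Extract the count matrix from a catalog tibble
#'
#' @param catalog A catalog tibble as built by [mutation_catalog()] or
#'   [read_catalog()].
#' @return Integer matrix with sample ids as rownames and categories as
#'   colnames, columns in canonical order.
#' @export
catalog_matrix <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  if (!"sample_id" %in% names(catalog)) {
    abort("catalog must have a 'sample_id' column")
  }
  cats <- setdiff(names(catalog), "sample_id")
  canon <- canonical_order(cats)
  m <- as.matrix(catalog[, canon, drop = FALSE])
  storage.mode(m) <- "double"
  validate_counts(m)
  rownames(m) <- catalog$sample_id
  if (anyDuplicated(rownames(m))) abort("duplicate sample ids in catalog")
  m
}

# Order a label set canonically: SBS-96 labels get the COSMIC order,
# anything else (toy category spaces in tests) is sorted lexicographically.
canonical_order <- function(labels) {
  canon <- sbs96_categories()
  if (setequal(labels, canon)) canon else sort(labels)
}

#' Build a signature set tibble
#'
#' Signature sets use the COSMIC table layout: one row per mutation
#' category (`category` column), one numeric column per signature, each
#' signature a probability distribution over categories.
#'
#' @param probs Numeric matrix, signatures in rows and categories in
#'   columns (each row sums to 1), or the transpose with categories in rows
#'   when `categories` matches its rownames.
#' @param signature_ids Character vector of signature names.
#' @param categories Category labels; canonical SBS-96 by default.
#' @return A tibble with `M` rows and `1 + K` columns.
#' @export
signature_set <- function(probs, signature_ids = NULL,
                          categories = sbs96_categories()) {
  probs <- as.matrix(probs)
  if (ncol(probs) == length(categories) && nrow(probs) != length(categories)) {
    probs <- t(probs) # came in signatures-by-categories
  }
  if (nrow(probs) != length(categories)) {
    abort("probs dimensions do not match the category set")
  }
  if (is.null(signature_ids)) {
    signature_ids <- colnames(probs) %||% paste0("Sig", seq_len(ncol(probs)))
  }
  colnames(probs) <- signature_ids
  out <- dplyr::bind_cols(
    tibble::tibble(category = categories),
    tibble::as_tibble(as.data.frame(probs, optional = TRUE))
  )
  validate_signature_set(out)
}

#' Extract the K x M signature probability matrix
#'
#' @param signatures A signature set tibble (see [signature_set()]).
#' @return Numeric matrix with one row per signature (rows sum to 1),
#'   columns in canonical category order.
#' @export
signature_matrix <- function(signatures) {
  stopifnot(is.data.frame(signatures))
  if (!"category" %in% names(signatures)) {
    abort("signature set must have a 'category' column")
  }
  canon <- canonical_order(signatures$category)
  idx <- match(canon, signatures$category)
  m <- t(as.matrix(signatures[idx, setdiff(names(signatures), "category"),
    drop = FALSE
  ]))
  colnames(m) <- canon
  m
}

validate_signature_set <- function(signatures, tol = 1e-6) {
  m <- signature_matrix(signatures)
  if (any(m < 0)) {
    bad <- rownames(m)[which(apply(m, 1, min) < 0)[1]]
    abort(sprintf("negative probability in signature '%s'", bad))
  }
  rs <- rowSums(m)
  off <- which(abs(rs - 1) > tol)
  if (length(off) > 0) {
    abort(sprintf(
      "signature '%s' sums to %.6f, not 1 (tolerance %g)",
      rownames(m)[off[1]], rs[off[1]], tol
    ))
  }
  # exact renormalization of sub-tolerance drift
  m <- m / rs
  out <- dplyr::bind_cols(
    tibble::tibble(category = colnames(m)),
    tibble::as_tibble(as.data.frame(t(m), optional = TRUE))
  )
  # keep the caller's row order
  out[match(signatures$category, out$category), ]
}

#' Number of samples / categories in a catalog
#' @param catalog A catalog tibble.
#' @return Integer count.
#' @export
n_samples <- function(catalog) nrow(catalog)

#' @rdname n_samples
#' @export
n_categories <- function(catalog) ncol(catalog) - 1L
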