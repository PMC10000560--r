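# Signature quality evaluation: cosine matching of learned signatures to a
# reference set (COSMIC-style), duplicate removal, and the effective number
# of signatures surviving panel-level down-sampling.

#' Match learned signatures to a reference set by cosine similarity
#'
#' Each learned signature is matched to its most similar reference
#' signature (greedy per-signature argmax, mirroring how de novo
#' signatures are usually reported). Pairs below `threshold` are dropped;
#' when several learned signatures hit the same reference, all but the
#' highest-cosine one are marked duplicates and excluded from the summed
#' similarity. `method = "optimal"` instead searches all assignments of
#' learned to distinct reference signatures for the maximal total cosine
#' (used by the parameter-recovery harness; exhaustive, so intended for
#' small K).
#'
#' @param learned,reference Signature set tibbles over the same category
#'   space.
#' @param threshold Minimum cosine similarity for a match (0.7 and 0.8 are
#'   the conventional cutoffs; default 0.8).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return A `match_report` list: `pairs` (tibble `learned_id`,
#'   `reference_id`, `cosine`, `duplicate`), `duplicates`, `n_matched`
#'   (unique retained matches), `summed_similarity`.
#' @export
match_signatures <- function(learned, reference, threshold = 0.8,
                             method = c("greedy", "optimal")) {
  method <- match.arg(method)
  le <- signature_matrix(learned)
  re <- signature_matrix(reference)
  if (ncol(le) != ncol(re) ||
    !identical(colnames(le), colnames(re))) {
    abort("learned and reference signatures use different category spaces")
  }
  zero <- rowSums(le^2) == 0
  if (any(zero)) {
    abort(sprintf(
      "signature '%s' is a zero vector: cosine similarity undefined",
      rownames(le)[which(zero)[1]]
    ))
  }
  cs <- cosine_matrix(le, re)
  if (method == "optimal") {
    assign <- best_assignment(cs)
    pairs <- tibble::tibble(
      learned_id = rownames(le),
      reference_id = rownames(re)[assign],
      cosine = cs[cbind(seq_len(nrow(le)), assign)],
      duplicate = FALSE
    )
  } else {
    best <- max.col(cs, ties.method = "first")
    pairs <- tibble::tibble(
      learned_id = rownames(le),
      reference_id = rownames(re)[best],
      cosine = cs[cbind(seq_len(nrow(cs)), best)]
    )
    pairs <- pairs[pairs$cosine >= threshold, , drop = FALSE]
    if (nrow(pairs) == 0) {
      pairs$duplicate <- logical(0)
    } else {
      pairs <- pairs |>
        dplyr::group_by(.data$reference_id) |>
        dplyr::mutate(duplicate = .data$cosine < max(.data$cosine) |
          (duplicated(.data$cosine) & .data$cosine == max(.data$cosine))) |>
        dplyr::ungroup()
    }
  }
  retained <- pairs[!pairs$duplicate, , drop = FALSE]
  structure(
    list(
      pairs = pairs,
      duplicates = pairs$learned_id[pairs$duplicate],
      n_matched = nrow(retained),
      summed_similarity = sum(retained$cosine),
      threshold = threshold,
      method = method
    ),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "Signature match report (threshold %.2f, %s matching)\n",
    x$threshold, x$method
  ))
  cat(sprintf(
    "  %d unique match(es), %d duplicate(s), summed cosine %.4f\n",
    x$n_matched, length(x$duplicates), x$summed_similarity
  ))
  invisible(x)
}

cosine_matrix <- function(a, b) {
  an <- a / sqrt(rowSums(a^2))
  bn <- b / sqrt(rowSums(b^2))
  tcrossprod(an, bn)
}

# Exhaustive assignment of rows to distinct columns maximizing total
# similarity (columns may be reused only if there are fewer columns than
# rows is disallowed: requires ncol >= nrow). Exponential in nrow; fine
# for the handful of signatures considered here.
best_assignment <- function(cs) {
  n <- nrow(cs)
  if (ncol(cs) < n) abort("optimal matching needs at least as many reference as learned signatures")
  perms <- permutations_of(seq_len(ncol(cs)), n)
  totals <- vapply(perms, function(p) sum(cs[cbind(seq_len(n), p)]), 0)
  perms[[which.max(totals)]]
}

permutations_of <- function(x, m) {
  if (m == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i], m - 1)) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' Effective number of signatures in a down-sampled catalog
#'
#' When a rich catalog is thinned to panel depth, some of the generating
#' signatures may no longer be visible. Using the known per-sample
#' exposures and signatures, every remaining mutation of category `j` in
#' sample `n` is attributed to the signature maximizing the a priori
#' probability `exposure[n, k] * e_k(j)` (ties broken toward the lowest
#' signature index); the effective K is the number of signatures holding
#' more than `fraction` of all attributed mutations.
#'
#' @param true_exposures N x K matrix of per-sample exposures (rows sum
#'   to 1), rows aligned with `downsampled`.
#' @param true_signatures Signature set tibble of the K generating
#'   signatures.
#' @param downsampled A catalog tibble or count matrix.
#' @param fraction Minimum share of attributed mutations (default 0.05).
#' @return Integer: the number of signatures above the share threshold
#'   (0 for an all-zero catalog).
#' @export
effective_k <- function(true_exposures, true_signatures, downsampled,
                        fraction = 0.05) {
  expos <- as.matrix(true_exposures)
  e <- signature_matrix(true_signatures)
  v <- if (is.data.frame(downsampled)) catalog_matrix(downsampled) else as.matrix(downsampled)
  stopifnot(nrow(expos) == nrow(v), ncol(expos) == nrow(e), ncol(e) == ncol(v))
  if (max(abs(rowSums(expos) - 1)) > 1e-6) {
    abort("exposure rows must sum to 1")
  }
  k <- nrow(e)
  tally <- numeric(k)
  for (n in seq_len(nrow(v))) {
    nz <- which(v[n, ] > 0)
    if (length(nz) == 0) next
    ap <- expos[n, ] * e[, nz, drop = FALSE] # K x |nz| a priori probabilities
    best <- apply(ap, 2L, which.max) # ties -> lowest index
    tally <- tally + vapply(
      seq_len(k),
      function(s) sum(v[n, nz][best == s]), 0
    )
  }
  total <- sum(tally)
  if (total == 0) return(0L)
  as.integer(sum(tally / total > fraction))
}
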