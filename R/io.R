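#' Read a mutation catalog from a delimited file
#'
#' Accepts tab- or comma-separated tables with one header row of SBS
#' category labels (samples as rows, the default convention for mutation
#' count matrices) or the transpose. Columns may appear in any order in the
#' file; the returned catalog is always in canonical category order.
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"samples-as-rows"` (default) or
#'   `"samples-as-columns"`.
#' @param categories Expected category label set (canonical SBS-96 by
#'   default); files missing labels or carrying unknown ones are rejected
#'   with the offending labels named.
#' @return A catalog tibble (see [mutation_catalog()]).
#' @export
read_catalog <- function(path,
                         orientation = c("samples-as-rows", "samples-as-columns"),
                         categories = sbs96_categories()) {
  orientation <- match.arg(orientation)
  tab <- read_delim_auto(path)
  if (ncol(tab) < 2) abort("catalog file must have an id column and count columns")
  if (orientation == "samples-as-columns") {
    cats <- as.character(tab[[1]])
    m <- t(as.matrix(tab[, -1, drop = FALSE]))
    colnames(m) <- cats
    rownames(m) <- names(tab)[-1]
  } else {
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (nrow(m) == 0) storage.mode(m) <- "integer" # header-only file
    rownames(m) <- as.character(tab[[1]])
  }
  check_categories(colnames(m), categories)
  if (!is.numeric(m)) abort("catalog counts must be numeric")
  validate_counts(m)
  mutation_catalog(m,
    sample_ids = rownames(m),
    categories = canonical_order(categories)
  )
}

#' Write a mutation catalog to a TSV file
#'
#' Inverse of [read_catalog()]: `read_catalog(write_catalog(x, f))` returns
#' `x` bit-exactly.
#'
#' @param catalog A catalog tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  m <- catalog_matrix(catalog) # validates
  readr::write_tsv(catalog, path)
  invisible(path)
}

#' Read a signature table in COSMIC layout
#'
#' COSMIC-style files store categories as rows (first column holds the SBS
#' label, commonly named `Type`) and one column per signature. Extra
#' annotation columns can be skipped with `columns`.
#'
#' @param path Path to a TSV/CSV file.
#' @param columns Optional character vector naming the signature columns to
#'   keep; by default every numeric column is used and non-numeric
#'   annotation columns are dropped.
#' @param tol Row-sum tolerance: each signature must sum to 1 within `tol`
#'   (then is renormalized exactly); larger deviations are an error.
#' @return A signature set tibble (see [signature_set()]).
#' @export
read_signatures <- function(path, columns = NULL, tol = 1e-6) {
  tab <- read_delim_auto(path)
  cats <- as.character(tab[[1]])
  check_categories(cats, canonical_order(cats))
  rest <- tab[, -1, drop = FALSE]
  if (is.null(columns)) {
    columns <- names(rest)[vapply(rest, is.numeric, TRUE)]
  } else {
    missing <- setdiff(columns, names(rest))
    if (length(missing) > 0) {
      abort(paste0("signature column(s) not in file: ", paste(missing, collapse = ", ")))
    }
  }
  if (length(columns) == 0) abort("no numeric signature columns found")
  probs <- as.matrix(rest[, columns, drop = FALSE])
  rownames(probs) <- cats
  canon <- canonical_order(cats)
  probs <- probs[canon, , drop = FALSE]
  out <- dplyr::bind_cols(
    tibble::tibble(category = canon),
    tibble::as_tibble(as.data.frame(probs, optional = TRUE))
  )
  validate_signature_set(out, tol = tol)
}

#' Write a signature set to a TSV file (COSMIC layout)
#'
#' @param signatures A signature set tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  readr::write_tsv(signatures, path)
  invisible(path)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    progress = FALSE, name_repair = "minimal"
  )
}

#' Serialize a fitted model to JSON
#'
#' Stores the parameters (`pi`, `e`, and for Mix models `w`), the category
#' order, the seed, and the iteration counts, at full double precision so a
#' round-trip reproduces the model exactly.
#'
#' @param model A `btm_model` or `mix_model`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("btm_model", "mix_model")))
  payload <- list(
    type = class(model)[1],
    k = model$k,
    categories = model$categories,
    pi = unclass(model$pi),
    e = unclass(model$e),
    seed = model$seed,
    n_seeds = model$n_seeds,
    burn_iters = model$burn_iters,
    final_iters = model$final_iters,
    train_ll = model$train_ll
  )
  if (inherits(model, "mix_model")) {
    payload$l <- model$l
    payload$w <- unclass(model$w)
  }
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor"
  )
  invisible(path)
}

#' Read a model serialized with [write_model()]
#'
#' @param path Path to the JSON file.
#' @return A `btm_model` or `mix_model` object.
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  e <- matrix(p$e, nrow = p$k, byrow = FALSE)
  if (is.matrix(p$e)) e <- p$e
  colnames(e) <- p$categories
  if (identical(p$type, "mix_model")) {
    pi <- p$pi
    if (!is.matrix(pi)) pi <- matrix(pi, nrow = p$l)
    out <- new_mix_model(
      w = as.numeric(p$w), pi = pi, e = e, seed = p$seed,
      train_ll = p$train_ll, categories = p$categories
    )
  } else {
    out <- new_btm_model(
      pi = as.numeric(p$pi), e = e, seed = p$seed,
      train_ll = p$train_ll, categories = p$categories
    )
  }
  out$n_seeds <- p$n_seeds
  out$burn_iters <- p$burn_iters
  out$final_iters <- p$final_iters
  out
}
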