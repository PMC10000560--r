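#' Canonical SBS-96 mutation categories
#'
#' The 96 single-base-substitution classes: six pyrimidine-centered
#' substitution types (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the four
#' possible 5' and 3' flanking bases. Labels follow the COSMIC convention,
#' e.g. `"A[C>A]A"`, and the canonical order is substitution type major,
#' then 5' base, then 3' base (each A, C, G, T).
#'
#' @return Character vector of the 96 category labels in canonical order.
#' @examples
#' head(sbs96_categories())
#' @export
sbs96_categories <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (five in bases) {
      for (three in bases) {
        out <- c(out, paste0(five, "[", s, "]", three))
      }
    }
  }
  out
}

#' Parse SBS category labels into substitution type and context
#'
#' @param categories Character vector of labels like `"A[C>A]A"`.
#' @return A tibble with columns `category`, `substitution`, `five_prime`,
#'   `three_prime`.
#' @export
parse_sbs_category <- function(categories) {
  m <- regmatches(
    categories,
    regexec("^([ACGT])\\[([CT]>[ACGT])\\]([ACGT])$", categories)
  )
  bad <- categories[lengths(m) == 0]
  if (length(bad) > 0) {
    abort(paste0(
      "not valid SBS category label(s): ",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  tibble::tibble(
    category = categories,
    five_prime = vapply(m, `[`, "", 2L),
    substitution = vapply(m, `[`, "", 3L),
    three_prime = vapply(m, `[`, "", 4L)
  )[, c("category", "substitution", "five_prime", "three_prime")]
}

# Check a label set against a canonical set; error names offenders.
check_categories <- function(labels, canonical = sbs96_categories()) {
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0) {
    abort(paste0("duplicate category label(s): ", paste(dup, collapse = ", ")))
  }
  missing <- setdiff(canonical, labels)
  extra <- setdiff(labels, canonical)
  if (length(missing) > 0 || length(extra) > 0) {
    msg <- character(0)
    if (length(missing) > 0) {
      msg <- c(msg, paste0(
        "missing category label(s): ",
        paste(utils::head(missing, 8), collapse = ", "),
        if (length(missing) > 8) sprintf(" (and %d more)", length(missing) - 8) else ""
      ))
    }
    if (length(extra) > 0) {
      msg <- c(msg, paste0(
        "unknown category label(s): ",
        paste(utils::head(extra, 8), collapse = ", ")
      ))
    }
    abort(paste(msg, collapse = "; "))
  }
  invisible(labels)
}
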