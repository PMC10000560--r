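# broom-style tidiers for the fitted objects and selection results.

#' Tidy a fitted Btm model
#'
#' @param x A `btm_model`.
#' @param ... Unused.
#' @return Tibble with one row per (signature, category):
#'   `signature`, `category`, `probability`, `exposure`.
#' @export
tidy.btm_model <- function(x, ...) {
  cats <- x$categories %||% colnames(x$e) %||% paste0("cat", seq_len(ncol(x$e)))
  tibble::tibble(
    signature = rep(paste0("BtmSig", seq_len(x$k)), each = ncol(x$e)),
    category = rep(cats, times = x$k),
    probability = as.vector(t(x$e)),
    exposure = rep(x$pi, each = ncol(x$e))
  )
}

#' @rdname tidy.btm_model
#' @export
glance.btm_model <- function(x, ...) {
  tibble::tibble(
    k = x$k, m = ncol(x$e), log_lik = x$train_ll,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a fitted Mix model
#'
#' @param x A `mix_model`.
#' @param ... Unused.
#' @return Tibble with one row per (signature, category) plus per-cluster
#'   exposures accessible via [mix_exposures()].
#' @export
tidy.mix_model <- function(x, ...) {
  cats <- x$categories %||% colnames(x$e) %||% paste0("cat", seq_len(ncol(x$e)))
  tibble::tibble(
    signature = rep(paste0("MixSig", seq_len(x$k)), each = ncol(x$e)),
    category = rep(cats, times = x$k),
    probability = as.vector(t(x$e))
  )
}

#' @rdname tidy.mix_model
#' @export
glance.mix_model <- function(x, ...) {
  tibble::tibble(
    l = x$l, k = x$k, m = ncol(x$e), log_lik = x$train_ll,
    n_parameters = mix_n_parameters(x$l, x$k, ncol(x$e)),
    seed = x$seed %||% NA_integer_
  )
}

#' Per-cluster exposures of a Mix model as a tibble
#'
#' @param model A `mix_model`.
#' @return Tibble with columns `cluster`, `weight`, `signature`,
#'   `exposure`.
#' @export
mix_exposures <- function(model) {
  tibble::tibble(
    cluster = rep(seq_len(model$l), each = model$k),
    weight = rep(model$w, each = model$k),
    signature = rep(paste0("MixSig", seq_len(model$k)), times = model$l),
    exposure = as.vector(t(model$pi))
  )
}

#' Tidy a Btm2K selection result
#'
#' @param x A `btm2k_result`.
#' @param ... Unused.
#' @return The per-repetition score table (`k`, `rep`, `score`).
#' @export
tidy.btm2k_result <- function(x, ...) {
  x$scores
}

#' @rdname tidy.btm2k_result
#' @export
glance.btm2k_result <- function(x, ...) {
  tibble::tibble(
    k_best = x$k_best, k_final = x$k_final,
    k_min = x$k_range[1], k_max = x$k_range[2],
    reps = x$reps, alpha = x$alpha, n_big_patients = length(x$big_ids)
  )
}
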