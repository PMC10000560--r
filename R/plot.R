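# ggplot2 visualizations: SBS-96 signature profiles in the conventional
# substitution-type-faceted barplot, and cross-validation score panels.

signature_profile_plot <- function(long, value_col = "probability") {
  is_sbs <- all(long$category %in% sbs96_categories())
  if (is_sbs) {
    ann <- parse_sbs_category(unique(long$category))
    long <- dplyr::left_join(long, ann, by = "category")
    long$category <- factor(long$category, levels = sbs96_categories())
    ggplot2::ggplot(long, ggplot2::aes(
      x = .data$category, y = .data[[value_col]], fill = .data$substitution
    )) +
      ggplot2::geom_col(width = 0.8) +
      ggplot2::facet_grid(signature ~ substitution,
        scales = "free_x", space = "free_x"
      ) +
      ggplot2::scale_fill_manual(values = c(
        "C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
        "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4"
      ), guide = "none") +
      ggplot2::labs(x = NULL, y = "probability") +
      ggplot2::theme_minimal(base_size = 9) +
      ggplot2::theme(
        axis.text.x = ggplot2::element_blank(),
        panel.grid.major.x = ggplot2::element_blank()
      )
  } else {
    ggplot2::ggplot(long, ggplot2::aes(
      x = .data$category, y = .data[[value_col]]
    )) +
      ggplot2::geom_col() +
      ggplot2::facet_wrap(~signature, ncol = 1) +
      ggplot2::labs(x = "category", y = "probability") +
      ggplot2::theme_minimal()
  }
}

#' Plot the signatures of a fitted Btm model
#'
#' Draws the conventional SBS-96 profile: one barplot row per signature,
#' faceted by substitution type.
#'
#' @param object A `btm_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.btm_model <- function(object, ...) {
  signature_profile_plot(tidy(object)) +
    ggplot2::ggtitle(sprintf(
      "Btm signatures (K = %d, global exposures %s)",
      object$k, paste(sprintf("%.2f", object$pi), collapse = "/")
    ))
}

#' Plot the shared signatures of a fitted Mix model
#'
#' @param object A `mix_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mix_model <- function(object, ...) {
  signature_profile_plot(tidy(object)) +
    ggplot2::ggtitle(sprintf(
      "Mix shared signatures (L = %d clusters, K = %d)", object$l, object$k
    ))
}

#' Plot Btm2K cross-validation scores
#'
#' One dot per repetition and candidate K, the per-K median as a line, and
#' the best-median and rolled-back K marked.
#'
#' @param object A `btm2k_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.btm2k_result <- function(object, ...) {
  med <- tibble::tibble(
    k = as.integer(names(object$per_k_medians)),
    score = unname(object$per_k_medians)
  )
  ggplot2::ggplot(object$scores, ggplot2::aes(x = .data$k, y = .data$score)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.5, size = 1) +
    ggplot2::geom_line(data = med, linetype = "dashed", color = "grey40") +
    ggplot2::geom_vline(
      xintercept = object$k_final, color = "grey70", linewidth = 3, alpha = 0.4
    ) +
    ggplot2::geom_vline(
      xintercept = object$k_best, color = "red", linetype = "dotted"
    ) +
    ggplot2::scale_x_continuous(breaks = unique(object$scores$k)) +
    ggplot2::labs(
      x = "number of signatures K", y = "held-out log-likelihood",
      title = sprintf(
        "Btm2K: best median K = %d, after rollback K = %d",
        object$k_best, object$k_final
      )
    ) +
    ggplot2::theme_minimal()
}
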