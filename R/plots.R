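#' Plot ranked entity scores
#'
#' Horizontal bar chart of the top-scoring entities (seeds excluded),
#' colored by concept.
#'
#' @param object A `kgqa_scores` object.
#' @param top_n Number of entities shown.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot kgqa_scores
#' @export
autoplot.kgqa_scores <- function(object, top_n = 15, ...) {
  tab <- tidy(object)
  tab <- tab[!tab$id %in% object$seeds, ]
  tab <- head(tab, top_n)
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$score, y = stats::reorder(.data$name, .data$score),
      fill = .data$concept
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "weighted path-ranking score", y = NULL, fill = "concept",
      title = sprintf("Entity scores (alpha = %.2f)", object$alpha)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-category decision accuracy
#'
#' @param object A `kgqa_eval` report.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot kgqa_eval
#' @export
autoplot.kgqa_eval <- function(object, ...) {
  ggplot2::ggplot(
    object$per_category,
    ggplot2::aes(x = .data$category, y = .data$accuracy)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$overall_accuracy, linetype = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "decision accuracy",
      title = sprintf("Per-category accuracy (overall %.3f)", object$overall_accuracy)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the strongest classifier features per category
#'
#' @param object A `kgqa_ig` model.
#' @param top_n Features per category.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot kgqa_ig
#' @export
autoplot.kgqa_ig <- function(object, top_n = 5, ...) {
  tab <- tidy(object)
  tab <- dplyr::slice_max(
    dplyr::group_by(tab, .data$category), .data$ig, n = top_n, with_ties = FALSE
  )
  ggplot2::ggplot(
    tab, ggplot2::aes(x = .data$ig, y = .data$feature)
  ) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::facet_wrap(~category, scales = "free_y") +
    ggplot2::labs(x = "information gain", y = NULL) +
    ggplot2::theme_minimal()
}
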