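# broom-style tidiers and ggplot2 autoplot methods for the result types

#' @rdname tidy-targetrank
#' @title Tidy and summarize targetrank results
#' @description `tidy()` returns the per-observation tibble behind a
#'   result object; `glance()` returns a one-row summary.
#' @param x A `ranked_genes`, `roc_result` or `evaluation_report` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.ranked_genes <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname tidy-targetrank
#' @export
glance.ranked_genes <- function(x, ...) {
  tibble::tibble(
    metric = attr(x, "metric") %||% "unknown",
    n_genes = nrow(x),
    n_mapped = sum(x$mapped),
    n_unmapped = sum(!x$mapped),
    top_gene = x$gene[x$rank == 1],
    top_score = x$score[x$rank == 1]
  )
}

#' @rdname tidy-targetrank
#' @export
tidy.roc_result <- function(x, ...) {
  x$points
}

#' @rdname tidy-targetrank
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tidy-targetrank
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

unclass_result <- function(x) {
  class(x) <- class(tibble::tibble())
  attr(x, "metric") <- NULL
  attr(x, "roc") <- NULL
  x
}

#' Plot a ranked gene table
#'
#' Score against rank on a log-scaled rank axis, with unmapped tail genes
#' (score 0) distinguished by shape.
#'
#' @param object A `ranked_genes` tibble.
#' @param top_n Show only the first `top_n` ranks (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_genes <- function(object, top_n = NULL, ...) {
  d <- tibble::as_tibble(unclass_result(object))
  if (!is.null(top_n)) d <- d[d$rank <= top_n, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$mapped), size = 1) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(
      x = "rank", y = "score",
      title = paste0("Candidate ranking (",
                     attr(object, "metric") %||% "score", ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object with the chance diagonal and the AUC in the
#'   subtitle.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = "ROC",
      subtitle = sprintf("AUC = %.3f (%d pos / %d neg)",
                         object$auc, object$n_pos, object$n_neg)
    ) +
    ggplot2::theme_minimal()
}
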