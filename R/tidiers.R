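# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a link-prediction ranking result
#'
#' @param x A `kge_ranking` from [evaluate_ranking()].
#' @param ... Unused.
#' @return One row per relation: `relation`, `mrr`, `n`.
#' @method tidy kge_ranking
#' @export
tidy.kge_ranking <- function(x, ...) x$by_relation

#' @rdname tidy.kge_ranking
#' @return For `glance()`: one row with `macro_mrr`, `micro_mrr`,
#'   `n_observations`, `part`, `filtered`, `type_filtered`.
#' @method glance kge_ranking
#' @export
glance.kge_ranking <- function(x, ...) {
  tibble(macro_mrr = x$macro_mrr, micro_mrr = x$micro_mrr,
         n_observations = nrow(x$observations), part = x$part,
         filtered = x$filtered, type_filtered = x$type_filtered)
}

#' Tidy a trained embedding fit
#'
#' @param x A `kge_fit` from [train_kge()].
#' @param ... Unused.
#' @return The per-epoch loss trace: `epoch`, `loss_kg`, `loss_align`,
#'   `total`.
#' @method tidy kge_fit
#' @export
tidy.kge_fit <- function(x, ...) x$trace

#' @rdname tidy.kge_fit
#' @method glance kge_fit
#' @export
glance.kge_fit <- function(x, ...) {
  tibble(scorer = x$model$scorer, loss = x$config$loss,
         dim = x$model$dim, epochs = nrow(x$trace),
         final_loss = if (nrow(x$trace)) tail(x$trace$total, 1) else NA_real_,
         align_lambda = x$config$align_lambda,
         text_method = x$config$text_method)
}

#' Plot a training loss trace
#'
#' @param object A `kge_fit`.
#' @param ... Unused.
#' @return A ggplot of total (and, when active, alignment) loss by epoch.
#' @method autoplot kge_fit
#' @export
autoplot.kge_fit <- function(object, ...) {
  tr <- object$trace |>
    tidyr::pivot_longer(c("loss_kg", "loss_align", "total"),
                        names_to = "component", values_to = "value")
  if (all(object$trace$loss_align == 0)) {
    tr <- filter(tr, .data$component != "loss_align")
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = paste0(object$model$scorer, " training (",
                                 object$config$loss, " loss)")) +
    ggplot2::theme_minimal()
}

#' Plot per-relation MRR of a ranking result
#'
#' @param object A `kge_ranking`.
#' @param ... Unused.
#' @return A ggplot bar chart of per-relation MRR with the macro average
#'   marked.
#' @method autoplot kge_ranking
#' @export
autoplot.kge_ranking <- function(object, ...) {
  ggplot2::ggplot(object$by_relation,
                  ggplot2::aes(x = stats::reorder(.data$relation,
                                                  -.data$mrr),
                               y = .data$mrr)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$macro_mrr,
                        linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "MRR",
                  title = paste0("Filtered link prediction (",
                                 object$part, ")"),
                  subtitle = paste0("macro MRR = ",
                                    signif(object$macro_mrr, 4))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a relation degree histogram
#'
#' Rank-frequency view of [relation_degree_histogram()] output, the lens
#' under which category-node imbalance is visible.
#'
#' @param degrees Tibble from [relation_degree_histogram()].
#' @param log_scale Use log10 axes.
#' @return A ggplot.
#' @export
plot_degree_histogram <- function(degrees, log_scale = TRUE) {
  df <- mutate(arrange(degrees, dplyr::desc(.data$n)),
               rank = row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "entity rank", y = "triple count") +
    ggplot2::theme_minimal()
  if (log_scale) {
    p <- p + ggplot2::scale_x_log10() + ggplot2::scale_y_log10()
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
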