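#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a molecular graph
#'
#' Draws the hydrogen-bond network with a force-directed (Fruchterman-
#' Reingold) layout, nodes colored by donor/acceptor role and singletons
#' shown faded.
#'
#' @param object A `mol_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mol_graph <- function(object, ...) {
  n <- nrow(object$nodes)
  ig <- igraph::graph_from_adjacency_matrix(
    (object$A != 0) * 1,
    mode = "undirected"
  )
  xy <- igraph::layout_with_fr(ig, niter = 200)
  nodes <- tibble::tibble(
    x = xy[, 1], y = xy[, 2],
    role = object$nodes$role,
    singleton = igraph::degree(ig) == 0
  )
  ed <- object$edges
  seg <- tibble::tibble(
    x = nodes$x[ed$i], y = nodes$y[ed$i],
    xend = nodes$x[ed$j], yend = nodes$y[ed$j]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      color = "grey60", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y, color = .data$role,
        alpha = !.data$singleton
      ),
      size = 2
    ) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.25), guide = "none") +
    ggplot2::labs(
      title = sprintf(
        "Hydrogen-bond graph: %d nodes, %d edges (%s)",
        n, nrow(ed), object$mode
      ),
      color = "role"
    ) +
    ggplot2::theme_void()
}

#' Plot per-split evaluation metrics
#'
#' Boxplots of accuracy, macro F1 and macro AUC-ROC across the repeated
#' stratified splits.
#'
#' @param object An `hb_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hb_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_split, c("accuracy", "f1", "auc"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = "score",
      title = sprintf("Test metrics over %d stratified splits", object$n_splits)
    ) +
    ggplot2::theme_minimal()
}

#' Plot the training loss trajectory
#'
#' @param object An `hb_gcn_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hb_gcn_model <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$epoch, y = .data$loss)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "epoch", y = "mean node cross-entropy",
      title = "Training loss"
    ) +
    ggplot2::theme_minimal()
}
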