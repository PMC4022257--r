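#' Plot an association network
#'
#' Draws the network with a seeded Fruchterman-Reingold layout; node shape
#' distinguishes OTUs from environmental factors and edge width scales with
#' mutual information.
#'
#' @param object An [assoc_network].
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assoc_network <- function(object, seed = 1, ...) {
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    dplyr::left_join(dplyr::select(nodes, "node", xa = "x", ya = "y"),
                     by = c(node_a = "node")) |>
    dplyr::left_join(dplyr::select(nodes, "node", xb = "x", yb = "y"),
                     by = c(node_b = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$xa, y = .data$ya, xend = .data$xb,
                   yend = .data$yb, linewidth = .data$weight),
      colour = "grey60", alpha = 0.6) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, shape = .data$type,
                   colour = .data$type), size = 2.5) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::scale_shape_manual(values = c(OTU = 16, env = 17)) +
    ggplot2::theme_void() +
    ggplot2::labs(shape = NULL, colour = NULL)
}

#' Plot a community model
#'
#' `type = "membership"` (default) draws the fuzzy membership matrix U as a
#' heatmap with nodes ordered by hard label; `type = "selection"` plots the
#' modularity Q_f across the candidate community counts r, marking the
#' selected model.
#'
#' @param object A [detect_communities()] model.
#' @param type `"membership"` or `"selection"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.community_model <- function(object,
                                     type = c("membership", "selection"),
                                     ...) {
  type <- match.arg(type)
  if (type == "selection") {
    sel <- object$selection
    return(
      ggplot2::ggplot(sel, ggplot2::aes(x = .data$r, y = .data$Q_f)) +
        ggplot2::geom_line() +
        ggplot2::geom_point() +
        ggplot2::geom_point(data = sel[sel$r == object$r, ],
                            colour = "red", size = 3) +
        ggplot2::labs(x = "number of communities r",
                      y = "fuzzy modularity Q_f") +
        ggplot2::theme_minimal()
    )
  }
  td <- tidy(object)
  node_order <- object$nodes[order(unname(object$labels))]
  td$node <- factor(td$node, levels = node_order)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$node,
                                   y = factor(.data$community),
                                   fill = .data$membership)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "community", fill = "U") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
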