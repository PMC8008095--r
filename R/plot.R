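#' Plot a ganglioside network
#'
#' Layered directed graph of the reaction network: nodes are structures
#' (labelled with their Svennerholm name where one exists), edges are
#' reactions colored by the class of transferred sugar, with the seed at
#' the left. Layout is the Sugiyama layered algorithm.
#'
#' @param object A `ganglio_network`.
#' @param label_size Node label size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ganglio_network <- function(object, label_size = 2.6, ...) {
  nodes <- object$nodes
  edges <- object$edges
  names_tbl <- glycan_names(nodes$identifier)
  nodes$label <- ifelse(is.na(names_tbl$ssn), names_tbl$identifier, names_tbl$ssn)

  if (nrow(edges) == 0L) {
    layout <- tibble(identifier = nodes$identifier, x = 0, y = seq_len(nrow(nodes)))
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("substrate", "product")],
      vertices = nodes$identifier, directed = TRUE
    )
    xy <- igraph::layout_with_sugiyama(g)$layout
    layout <- tibble(
      identifier = igraph::V(g)$name,
      x = xy[, 2], # layers run left to right
      y = xy[, 1]
    )
  }
  nodes <- dplyr::left_join(nodes, layout, by = "identifier")

  sugar_class <- c(
    "UDP-G" = "glucosyl", "UDP-L" = "galactosyl",
    "UDP-V" = "N-acetylgalactosaminyl", "CMP-S" = "sialyl"
  )
  palette <- c(
    glucosyl = "#2166ac", galactosyl = "#e6b800",
    "N-acetylgalactosaminyl" = "#8c510a", sialyl = "#c51b8a"
  )
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0L) {
    seg <- dplyr::left_join(
      edges, stats::setNames(layout, c("substrate", "x", "y")), by = "substrate"
    )
    seg <- dplyr::left_join(
      seg, stats::setNames(layout, c("product", "xend", "yend")), by = "product"
    )
    seg$transfer <- factor(sugar_class[seg$donor], levels = names(palette))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   color = .data$transfer),
      arrow = grid::arrow(length = grid::unit(1.6, "mm"), type = "closed"),
      linewidth = 0.4, alpha = 0.8
    )
  }
  p +
    ggplot2::geom_label(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = label_size, label.padding = grid::unit(0.12, "lines")
    ) +
    ggplot2::scale_color_manual(values = palette, drop = FALSE, name = "transferred sugar") +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "bottom")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.ganglio_network <- function(x, ...) print(autoplot(x, ...))

#' Bar chart of a knockout scan
#'
#' Structures and reactions remaining under each single-enzyme knockout,
#' side by side with the wild type.
#'
#' @param scan A list from [knockout_scan()].
#' @return A ggplot object.
#' @export
plot_knockout_summary <- function(scan) {
  summ <- knockout_summary(scan)
  long <- tidyr::pivot_longer(
    summ[, c("condition", "n_structures", "n_reactions")],
    cols = c("n_structures", "n_reactions"),
    names_to = "quantity", values_to = "count"
  )
  long$condition <- factor(long$condition, levels = summ$condition)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$condition, y = .data$count, fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(
      values = c(n_structures = "#4393c3", n_reactions = "#d6604d"),
      labels = c(n_structures = "structures", n_reactions = "reactions"),
      name = NULL
    ) +
    ggplot2::labs(x = "knocked-out enzyme", y = "count") +
    ggplot2::theme_minimal()
}
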