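#' Volcano plot of a differential-expression table
#'
#' @param de A [de_analysis()] result (needs `log_fc`, `adj_p`,
#'   `direction`).
#' @param lfc_cutoff,alpha Guide lines to draw (defaults match
#'   [call_directions()]).
#' @return A ggplot.
#' @export
plot_volcano <- function(de, lfc_cutoff = 1.5, alpha = 0.05) {
  ggplot2::ggplot(de, ggplot2::aes(x = .data$log_fc,
                                   y = -log10(.data$adj_p),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_cutoff, lfc_cutoff),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue",
                                            ns = "grey60")) +
    ggplot2::labs(x = "log2 fold change (tumor - normal)",
                  y = "-log10 adjusted p")
}

#' Plot a ceRNA network
#'
#' Deterministic force-directed layout; node shape encodes the molecule
#' class, colour the DE direction.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.cerna_network <- function(object, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void() +
             ggplot2::labs(title = "empty network"))
  }
  g <- as_igraph_cerna(object)
  set.seed(1L)
  xy <- igraph::layout_with_fr(g)
  nodes <- object$nodes |>
    mutate(x = xy[match(.data$id, igraph::V(g)$name), 1],
           y = xy[match(.data$id, igraph::V(g)$name), 2])
  edges <- object$edges |>
    mutate(x = nodes$x[match(.data$source, nodes$id)],
           y = nodes$y[match(.data$source, nodes$id)],
           xend = nodes$x[match(.data$target, nodes$id)],
           yend = nodes$y[match(.data$target, nodes$id)])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type,
                                     colour = .data$direction), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(up = "firebrick",
                                            down = "steelblue")) +
    ggplot2::theme_void()
}

#' Bar plot of hub-gene degrees
#'
#' @param hubs A [hub_genes()] tibble.
#' @return A ggplot.
#' @export
plot_hub_degrees <- function(hubs) {
  ggplot2::ggplot(hubs,
                  ggplot2::aes(x = stats::reorder(.data$gene_id, .data$degree),
                               y = .data$degree)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "PPI degree")
}
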