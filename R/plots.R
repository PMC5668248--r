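# ggplot2 views of the main result types.

#' Plot a folded structure as a position/arc diagram
#'
#' Base pairs are drawn as arcs over the sequence axis; arm classes are
#' shown along the baseline.
#'
#' @param object A `mir_fold`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_fold <- function(object, ...) {
  td <- tidy(object)
  arcs <- dplyr::filter(td, .data$paired & .data$partner > .data$position)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$position, y = 0)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$arm), size = 1) +
    ggplot2::labs(
      x = "position", y = NULL,
      title = sprintf("MFE %.2f kcal/mol, %d pairs", object$mfe, object$n_pairs),
      colour = "region"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
  if (nrow(arcs) > 0L) {
    p <- p + ggplot2::geom_curve(
      data = arcs,
      ggplot2::aes(
        x = .data$position, xend = .data$partner, y = 0, yend = 0
      ),
      curvature = -0.4, linewidth = 0.2, colour = "grey40"
    )
  }
  p
}

#' Plot a degree distribution
#'
#' Bars of p(k), the fraction of nodes with degree k.
#'
#' @param object A `mir_degree_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_degree_profile <- function(object, ...) {
  ggplot2::ggplot(
    object$distribution,
    ggplot2::aes(x = factor(.data$k), y = .data$p)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "degree k", y = "p(k)") +
    ggplot2::theme_minimal()
}

#' Plot a bipartite miRNA-target network
#'
#' miRNAs on the left, targets on the right, edges between.
#'
#' @param object A `mir_bipartite`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_bipartite <- function(object, ...) {
  g <- object$graph
  nodes <- tibble::tibble(
    name = igraph::V(g)$name, side = igraph::V(g)$side
  )
  nodes <- dplyr::mutate(
    dplyr::group_by(nodes, .data$side),
    x = ifelse(.data$side == "mirna", 0, 1),
    y = seq_along(.data$name) / max(1L, dplyr::n())
  )
  nodes <- dplyr::ungroup(nodes)
  edges <- edge_tibble(g)
  edges <- dplyr::left_join(
    edges, dplyr::select(nodes, "name", x0 = "x", y0 = "y"),
    by = c(from = "name")
  )
  edges <- dplyr::left_join(
    edges, dplyr::select(nodes, "name", x1 = "x", y1 = "y"),
    by = c(to = "name")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1
      ),
      colour = "grey70", linewidth = 0.3
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$side), size = 2
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' Scatter plot of shared-target expression between two conditions
#'
#' One point per shared target; the diagonal marks equal expression, and
#' points are coloured by the regulation call.
#'
#' @param object A `mir_condition_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_condition_comparison <- function(object, ...) {
  td <- dplyr::filter(tidy(object), !is.na(.data$fpkm_a) & !is.na(.data$fpkm_b))
  ggplot2::ggplot(
    td,
    ggplot2::aes(
      x = .data$fpkm_a, y = .data$fpkm_b, colour = .data$regulation
    )
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = paste0("FPKM (", object$condition_a, ")"),
      y = paste0("FPKM (", object$condition_b, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a co-expression network
#'
#' Force-directed layout (deterministic seed) with edge width by the
#' combined score.
#'
#' @param object A `mir_coexpr_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mir_coexpr_network <- function(object, ...) {
  g <- object$graph
  if (igraph::vcount(g) == 0L) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  lay <- withr::with_seed(
    1L, igraph::layout_with_fr(g)
  )
  nodes <- tibble::tibble(
    name = igraph::V(g)$name, x = lay[, 1], y = lay[, 2]
  )
  edges <- edge_tibble(g)
  edges <- dplyr::left_join(
    edges, dplyr::select(nodes, "name", x0 = "x", y0 = "y"),
    by = c(from = "name")
  )
  edges <- dplyr::left_join(
    edges, dplyr::select(nodes, "name", x1 = "x", y1 = "y"),
    by = c(to = "name")
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$weight
      ),
      colour = "grey70"
    ) +
    ggplot2::scale_linewidth(range = c(0.1, 1)) +
    ggplot2::geom_point(data = nodes, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::theme_void()
}
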