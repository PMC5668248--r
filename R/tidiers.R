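# broom-style tidy()/glance() methods for the pipeline's result objects.

#' @rdname mirframe-tidiers
#' @param x A mirframe result object.
#' @param ... Unused.
#' @export
tidy.mir_fold <- function(x, ...) {
  tibble::tibble(
    position = seq_len(nchar(x$sequence)),
    base = strsplit(x$sequence, "", fixed = TRUE)[[1]],
    partner = x$pair_table,
    paired = x$pair_table > 0L,
    arm = arm_of(x)
  )
}

#' Tidiers for mirframe result objects
#'
#' `tidy()` returns the per-element tibble underlying a result
#' (positions of a fold, edges of a network, endpoint-degree pairs of a
#' degree correlation, scored candidates of a co-expression network);
#' `glance()` returns a one-row summary.
#'
#' @name mirframe-tidiers
#' @inheritParams tidy.mir_fold
#' @export
glance.mir_fold <- function(x, ...) {
  tibble::tibble(
    length = nchar(x$sequence), n_pairs = x$n_pairs, mfe = x$mfe
  )
}

#' @rdname mirframe-tidiers
#' @export
tidy.mir_bipartite <- function(x, ...) {
  edge_tibble(x$graph)
}

#' @rdname mirframe-tidiers
#' @export
glance.mir_bipartite <- function(x, ...) {
  side <- igraph::V(x$graph)$side
  tibble::tibble(
    condition = x$condition,
    n_mirnas = sum(side == "mirna"),
    n_targets = sum(side == "target"),
    n_edges = igraph::ecount(x$graph)
  )
}

#' @rdname mirframe-tidiers
#' @export
tidy.mir_degree_profile <- function(x, ...) x$degrees

#' @rdname mirframe-tidiers
#' @export
glance.mir_degree_profile <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$degrees),
    mean_degree = mean(x$degrees$degree),
    max_degree = if (nrow(x$degrees)) max(x$degrees$degree) else NA_integer_
  )
}

#' @rdname mirframe-tidiers
#' @export
tidy.mir_degree_correlation <- function(x, ...) x$pairs

#' @rdname mirframe-tidiers
#' @export
glance.mir_degree_correlation <- function(x, ...) {
  tibble::tibble(r = x$r, m = x$m)
}

#' @rdname mirframe-tidiers
#' @export
tidy.mir_condition_comparison <- function(x, ...) {
  dplyr::select(
    x$common_targets, "target_key", "fpkm_a", "fpkm_b", "regulation"
  )
}

#' @rdname mirframe-tidiers
#' @export
glance.mir_condition_comparison <- function(x, ...) {
  tibble::tibble(
    condition_a = x$condition_a, condition_b = x$condition_b,
    n_common_mirnas = length(x$common_mirnas),
    n_unique_a = length(x$unique_mirnas_a),
    n_unique_b = length(x$unique_mirnas_b),
    n_common_targets = nrow(x$common_targets)
  )
}

#' @rdname mirframe-tidiers
#' @export
tidy.mir_coexpr_network <- function(x, ...) x$records

#' @rdname mirframe-tidiers
#' @export
glance.mir_coexpr_network <- function(x, ...) {
  tibble::tibble(
    n_genes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    w_abundance = unname(x$weights[1]),
    w_go = unname(x$weights[2]),
    w_pcc = unname(x$weights[3])
  )
}

#' @rdname mirframe-tidiers
#' @export
tidy.mir_go_clusters <- function(x, ...) x$clusters

#' @rdname mirframe-tidiers
#' @export
glance.mir_go_clusters <- function(x, ...) {
  tibble::tibble(
    n_clusters = nrow(x$members),
    n_transcripts = nrow(x$clusters),
    n_edges = nrow(x$edges)
  )
}
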