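# Weighted co-expression network reconstruction: per-candidate component
# scores (abundance, GO overlap, expression correlation), a weighted
# combined score, and top-k neighbour selection per query gene.

#' Default co-expression weights
#'
#' Abundance 0.4, GO 0.3, PCC 0.3; the weights sum to 1.
#'
#' @return Named numeric vector `c(abundance, go, pcc)`.
#' @export
coexpression_weights <- function() {
  c(abundance = 0.4, go = 0.3, pcc = 0.3)
}

#' Component scores of candidate genes against a query gene
#'
#' For every candidate: `abundance_score` is the candidate's mean FPKM
#' rank-normalized to \[0, 1\] across the candidate pool (average ranks on
#' ties; a single candidate scores 1); `go_score` is the Jaccard overlap
#' of the direct GO annotation sets of query and candidate; `pcc_score`
#' is `(r + 1) / 2` where r is the Pearson correlation of the two genes'
#' FPKM vectors across all (condition, replicate) samples. All components
#' are clipped to \[0, 1\].
#'
#' @param query Query gene id (must be present in `expression`).
#' @param candidates Candidate gene ids (default: all other genes in
#'   `expression`).
#' @param expression Long expression table.
#' @param annotations Tibble `transcript_id`, `go_term` (optional; GO
#'   scores are 0 without it).
#' @return Tibble `query_gene`, `candidate_gene`, `abundance_score`,
#'   `go_score`, `pcc_score`.
#' @export
component_scores <- function(query, candidates = NULL, expression,
                             annotations = NULL) {
  expression <- as_expression_table(expression)
  genes <- unique(expression$transcript_id)
  if (!query %in% genes) abort(paste0("no expression for query gene: ", query))
  candidates <- candidates %||% setdiff(genes, query)
  missing <- setdiff(candidates, genes)
  if (length(missing) > 0L) {
    abort(paste0(
      "no expression for candidate gene(s): ",
      paste(head(missing, 5L), collapse = ", ")
    ))
  }
  # sample-matched FPKM matrix
  wide <- tidyr::pivot_wider(
    dplyr::transmute(
      expression,
      sample = paste(.data$condition, .data$replicate, sep = "."),
      transcript_id = .data$transcript_id, fpkm = .data$fpkm
    ),
    names_from = "sample", values_from = "fpkm"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$transcript_id

  mean_fpkm <- rowMeans(mat[candidates, , drop = FALSE], na.rm = TRUE)
  n <- length(candidates)
  abundance <- if (n == 1L) 1 else (rank(mean_fpkm) - 1) / (n - 1)

  go_sets <- list()
  if (!is.null(annotations)) {
    ann <- dplyr::distinct(tibble::as_tibble(annotations))
    go_sets <- split(ann$go_term, ann$transcript_id)
  }
  q_terms <- go_sets[[query]] %||% character(0)
  go <- vapply(candidates, function(g) {
    g_terms <- go_sets[[g]] %||% character(0)
    u <- union(q_terms, g_terms)
    if (length(u) == 0L) 0 else length(intersect(q_terms, g_terms)) / length(u)
  }, numeric(1))

  qv <- mat[query, ]
  pcc <- vapply(candidates, function(g) {
    gv <- mat[g, ]
    ok <- !is.na(qv) & !is.na(gv)
    if (sum(ok) < 3L || stats::sd(qv[ok]) == 0 || stats::sd(gv[ok]) == 0) {
      return(0.5) # undefined correlation maps to the neutral midpoint
    }
    (stats::cor(qv[ok], gv[ok]) + 1) / 2
  }, numeric(1))

  tibble::tibble(
    query_gene = query,
    candidate_gene = candidates,
    abundance_score = pmin(1, pmax(0, unname(abundance))),
    go_score = pmin(1, pmax(0, unname(go))),
    pcc_score = pmin(1, pmax(0, unname(pcc)))
  )
}

#' Weighted combined co-expression score
#'
#' `combined = w_abundance * abundance + w_go * go + w_pcc * pcc`; the
#' weights must be non-negative and sum to 1 (default 0.4/0.3/0.3), so a
#' gene maximal in all three components scores exactly 1.
#'
#' @param components Tibble with `abundance_score`, `go_score`,
#'   `pcc_score` (e.g. from [component_scores()]), or a numeric vector of
#'   the three components.
#' @param weights Numeric weights (abundance, go, pcc).
#' @return The input tibble with a `combined` column, or a single number
#'   for vector input.
#' @export
#' @examples
#' combined_score(c(1, 1, 1))
combined_score <- function(components, weights = coexpression_weights()) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    abort("weights must be non-negative and sum to 1")
  }
  if (is.numeric(components)) {
    stopifnot(length(components) == 3L)
    return(sum(weights * components))
  }
  needed <- c("abundance_score", "go_score", "pcc_score")
  stopifnot(all(needed %in% names(components)))
  components$combined <- weights[1] * components$abundance_score +
    weights[2] * components$go_score +
    weights[3] * components$pcc_score
  components
}

#' Top-k co-expression neighbours of a query gene
#'
#' Candidates are sorted by descending combined score (ties broken by
#' ascending candidate gene id) and truncated to `k`; fewer than `k`
#' candidates are all kept.
#'
#' @param records Tibble with `candidate_gene` and `combined` (from
#'   [combined_score()]).
#' @param k Neighbourhood size (default 20).
#' @return The top rows of `records`.
#' @export
top_k_neighbors <- function(records, k = 20L) {
  stopifnot(k >= 1L)
  records <- dplyr::arrange(
    records, dplyr::desc(.data$combined), .data$candidate_gene
  )
  head(records, k)
}

#' Build the co-expression network for a set of query genes
#'
#' For each query gene the candidate pool is scored
#' ([component_scores()]), combined with `weights`
#' ([combined_score()]) and truncated to the top `k` neighbours
#' ([top_k_neighbors()]); the per-query fragments are merged into one
#' undirected graph with the combined score as edge weight.
#'
#' @param queries Character vector of query gene ids (must all have
#'   expression).
#' @param expression Long expression table.
#' @param annotations Optional GO annotations.
#' @param weights Component weights (default 0.4/0.3/0.3).
#' @param k Neighbours per query (default 20).
#' @param candidates Candidate pool (default: all non-query genes in
#'   `expression`).
#' @return A `mir_coexpr_network`: list with `graph` (undirected igraph,
#'   edge attribute `weight`), `records` (all scored candidates with
#'   `kept` flag) and the weights used.
#' @export
build_coexpression_network <- function(queries, expression,
                                       annotations = NULL,
                                       weights = coexpression_weights(),
                                       k = 20L, candidates = NULL) {
  if (length(queries) == 0L) {
    warn("empty query set: returning an empty co-expression network")
    return(structure(
      list(
        graph = igraph::make_empty_graph(directed = FALSE),
        records = tibble::tibble(), weights = weights
      ),
      class = "mir_coexpr_network"
    ))
  }
  expression <- as_expression_table(expression)
  records <- purrr::map_dfr(queries, function(q) {
    pool <- candidates %||%
      setdiff(unique(expression$transcript_id), queries)
    comp <- component_scores(
      q, setdiff(pool, q), expression, annotations
    )
    comp <- combined_score(comp, weights)
    kept <- top_k_neighbors(comp, k)
    comp$kept <- comp$candidate_gene %in% kept$candidate_gene
    comp
  })
  edges <- dplyr::filter(records, .data$kept)
  g <- igraph::graph_from_data_frame(
    dplyr::transmute(
      edges,
      from = .data$query_gene, to = .data$candidate_gene,
      weight = .data$combined
    ),
    directed = FALSE,
    vertices = sort(unique(c(edges$query_gene, edges$candidate_gene)))
  )
  structure(
    list(graph = g, records = records, weights = weights),
    class = "mir_coexpr_network"
  )
}

#' @export
print.mir_coexpr_network <- function(x, ...) {
  cat("<mir_coexpr_network>", igraph::vcount(x$graph), "genes,",
    igraph::ecount(x$graph), "edges (weights",
    paste(x$weights, collapse = "/"), ")\n"
  )
  invisible(x)
}
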