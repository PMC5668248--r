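# GO node-score network: a term's score is the annotation count over its
# descendant closure, decayed by alpha per edge of distance; transcripts
# are scored through their direct annotations and clustered by score.

# children adjacency (parent -> children) as a named list
dag_children <- function(dag) {
  split(dag$edges$child, factor(dag$edges$parent, levels = dag$terms$id))
}

# descendant closure of `term` with shortest descending distance
# (term itself at distance 0); BFS over reversed is_a edges
descendant_distances <- function(dag, term) {
  if (!term %in% dag$terms$id) {
    abort(paste0("unknown GO term: ", term))
  }
  kids <- dag_children(dag)
  dist <- c(setNames(0L, term))
  frontier <- term
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    nxt <- unique(unlist(kids[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt) == 0L) break
    dist <- c(dist, setNames(rep(d, length(nxt)), nxt))
    frontier <- nxt
  }
  dist
}

#' Node score of a GO term
#'
#' The score of term g is \eqn{\sum_{g_a \in desc(g)} gp(g_a) \cdot
#' \alpha^{dist(g, g_a)}}, where desc(g) is the descendant closure of g
#' (g itself included at distance 0), gp the per-term gene count, dist
#' the shortest descending is_a path length, and alpha a decay in (0, 1].
#' At alpha = 1 the score is the plain annotation total of the subtree.
#'
#' @param dag A `mir_go_dag`.
#' @param term Term id.
#' @param gene_counts Named numeric vector (or tibble `go_term`/`term`,
#'   `count`) of gene counts per term; missing terms count 0.
#' @param alpha Decay per edge, in (0, 1] (default 0.6).
#' @return The node score (non-negative real).
#' @export
#' @examples
#' # chain parent -> child with gp(parent) = 1, gp(child) = 2, alpha 0.5
#' dag <- make_go(simulation_config(seed = 1))$dag
node_score <- function(dag, term, gene_counts, alpha = 0.6) {
  if (!(alpha > 0 && alpha <= 1)) abort("alpha must be in (0, 1]")
  counts <- as_gene_counts(gene_counts)
  dist <- descendant_distances(dag, term)
  gp <- counts[names(dist)]
  gp[is.na(gp)] <- 0
  sum(gp * alpha^dist)
}

as_gene_counts <- function(gene_counts) {
  if (is.data.frame(gene_counts)) {
    term_col <- intersect(c("go_term", "term", "id"), names(gene_counts))[1]
    if (is.na(term_col) || !"count" %in% names(gene_counts)) {
      abort("gene_counts needs a term column and a count column")
    }
    return(setNames(gene_counts$count, gene_counts[[term_col]]))
  }
  if (is.null(names(gene_counts))) abort("gene_counts must be named by term")
  gene_counts
}

#' Score transcripts through their GO annotations
#'
#' A transcript's score is the sum of [node_score()] over its directly
#' annotated terms in the chosen namespace; per-term gene counts gp are
#' derived from the annotation set itself (number of distinct transcripts
#' directly annotated to the term). Duplicate annotations are collapsed
#' first. Transcripts without annotation in the namespace score 0 (with a
#' note).
#'
#' @param dag A `mir_go_dag`.
#' @param annotations Tibble `transcript_id`, `go_term`.
#' @param alpha Decay per edge (default 0.6).
#' @param namespace `"BP"`, `"MF"` or `"CC"`.
#' @return Tibble `transcript_id`, `score`, sorted by descending score
#'   then id.
#' @export
score_transcripts <- function(dag, annotations, alpha = 0.6,
                              namespace = c("BP", "MF", "CC")) {
  namespace <- match.arg(namespace)
  ann <- as_go_annotations(annotations, dag)
  ns_terms <- dag$terms$id[dag$terms$namespace == namespace]
  ann_ns <- dplyr::filter(ann, .data$go_term %in% ns_terms)
  counts <- dplyr::count(ann_ns, .data$go_term, name = "count")
  gp <- setNames(counts$count, counts$go_term)
  term_scores <- vapply(
    unique(ann_ns$go_term),
    function(g) node_score(dag, g, gp, alpha = alpha),
    numeric(1)
  )
  per_tx <- dplyr::summarise(
    dplyr::group_by(ann_ns, .data$transcript_id),
    score = sum(term_scores[.data$go_term]), .groups = "drop"
  )
  missing <- setdiff(unique(ann$transcript_id), per_tx$transcript_id)
  if (length(missing) > 0L) {
    inform(paste0(
      length(missing), " transcript(s) without ", namespace,
      " annotation score 0"
    ))
    per_tx <- dplyr::bind_rows(
      per_tx,
      tibble::tibble(transcript_id = missing, score = 0)
    )
  }
  dplyr::arrange(per_tx, dplyr::desc(.data$score), .data$transcript_id)
}

#' Cluster transcripts by node score
#'
#' Transcripts whose scores agree within a relative tolerance
#' (`|a - b| <= tolerance * max(1, |a|)`, compared against the cluster's
#' first member) fall into one cluster; clusters are labelled C1, C2, ...
#' by descending score. Inter-cluster edges are weighted by the number of
#' GO terms shared between the clusters' members (shared-ancestry
#' weighting of the direct annotations).
#'
#' @param scores Tibble `transcript_id`, `score` (from
#'   [score_transcripts()]).
#' @param annotations Tibble `transcript_id`, `go_term` used for edge
#'   weights (optional; without it all weights are 0).
#' @param tolerance Relative score tolerance (default 1e-9).
#' @return A `mir_go_clusters`: list with `clusters` (tibble
#'   `cluster`, `transcript_id`, `score`), `members` summary and `edges`
#'   (tibble `from`, `to`, `weight`).
#' @export
cluster_by_score <- function(scores, annotations = NULL, tolerance = 1e-9) {
  stopifnot(tolerance >= 0)
  scores <- dplyr::arrange(
    tibble::as_tibble(scores),
    dplyr::desc(.data$score), .data$transcript_id
  )
  cluster <- integer(nrow(scores))
  rep_score <- numeric(0)
  for (r in seq_len(nrow(scores))) {
    s <- scores$score[r]
    placed <- FALSE
    if (length(rep_score) > 0L) {
      last <- length(rep_score)
      if (abs(s - rep_score[last]) <= tolerance * max(1, abs(rep_score[last]))) {
        cluster[r] <- last
        placed <- TRUE
      }
    }
    if (!placed) {
      rep_score <- c(rep_score, s)
      cluster[r] <- length(rep_score)
    }
  }
  clusters <- dplyr::mutate(scores, cluster = paste0("C", cluster))
  members <- dplyr::summarise(
    dplyr::group_by(clusters, .data$cluster),
    score = .data$score[1], n = dplyr::n(), .groups = "drop"
  )
  members <- dplyr::arrange(members, dplyr::desc(.data$score))
  edges <- tibble::tibble(
    from = character(), to = character(), weight = double()
  )
  if (!is.null(annotations) && nrow(members) > 1L) {
    ann <- dplyr::distinct(tibble::as_tibble(annotations))
    term_sets <- lapply(
      split(clusters$transcript_id, clusters$cluster),
      function(tx) unique(ann$go_term[ann$transcript_id %in% tx])
    )
    combs <- utils::combn(members$cluster, 2)
    edges <- tibble::tibble(
      from = combs[1, ], to = combs[2, ],
      weight = apply(combs, 2, function(pr) {
        length(intersect(term_sets[[pr[1]]], term_sets[[pr[2]]]))
      })
    )
  }
  structure(
    list(clusters = clusters, members = members, edges = edges),
    class = "mir_go_clusters"
  )
}

#' @export
print.mir_go_clusters <- function(x, ...) {
  cat("<mir_go_clusters>", nrow(x$members), "clusters,",
    nrow(x$clusters), "transcripts\n"
  )
  invisible(x)
}

#' Filter clusters by minimum representative score
#'
#' Clusters whose representative score is at least `min_score` are kept
#' with the edges between surviving clusters; raising `min_score` never
#' adds nodes.
#'
#' @param network A `mir_go_clusters`.
#' @param min_score Minimum score (default 0).
#' @return A filtered `mir_go_clusters`.
#' @export
filter_top_nodes <- function(network, min_score = 0) {
  stopifnot(min_score >= 0)
  keep <- network$members$cluster[network$members$score >= min_score]
  structure(
    list(
      clusters = dplyr::filter(network$clusters, .data$cluster %in% keep),
      members = dplyr::filter(network$members, .data$cluster %in% keep),
      edges = dplyr::filter(
        network$edges, .data$from %in% keep & .data$to %in% keep
      )
    ),
    class = "mir_go_clusters"
  )
}
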