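# Network export/import: SIF, GraphML (via igraph) and edge-list TSV.
# Node and edge order is made deterministic (lexicographic) before writing.

#' Write a network to SIF, GraphML or edge-list TSV
#'
#' Nodes and edges are sorted lexicographically before writing so output
#' is byte-stable. For bipartite networks the side of each node is
#' recorded as a node attribute (`side`; GraphML only, since SIF and TSV
#' carry no node attributes).
#'
#' @param graph An `igraph` object (or an object with a `$graph` field,
#'   e.g. `mir_bipartite` / `mir_coexpr_network`).
#' @param path Output path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @param interaction Interaction label used in SIF output.
#' @return `path`, invisibly.
#' @export
write_network <- function(graph, path, format = c("sif", "graphml", "tsv"),
                          interaction = "targets") {
  if (!igraph::is_igraph(graph)) {
    if (is.list(graph) && igraph::is_igraph(graph$graph)) {
      graph <- graph$graph
    } else {
      abort("`graph` must be an igraph object or contain one in $graph")
    }
  }
  format <- match.arg(format)
  graph <- canonical_graph(graph)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
    return(invisible(path))
  }
  edges <- edge_tibble(graph)
  if (format == "sif") {
    lines <- if (nrow(edges) == 0L) character(0) else {
      paste(edges$from, interaction, edges$to, sep = "\t")
    }
    # isolated nodes are legal SIF: a bare node name line
    isolated <- setdiff(igraph::V(graph)$name, c(edges$from, edges$to))
    writeLines(c(lines, isolated), path)
  } else {
    readr::write_tsv(edges, path)
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path Input path.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @param directed For SIF/TSV input, whether edges are directed.
#' @return An `igraph` object.
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv"),
                         directed = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  if (format == "sif") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[stringr::str_trim(lines) != ""]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    edges <- purrr::keep(parts, ~ length(.x) >= 3L)
    nodes <- unlist(purrr::keep(parts, ~ length(.x) == 1L))
    df <- if (length(edges)) {
      tibble::tibble(
        from = vapply(edges, `[[`, "", 1L),
        to = vapply(edges, `[[`, "", 3L)
      )
    } else {
      tibble::tibble(from = character(), to = character())
    }
    verts <- unique(c(df$from, df$to, nodes))
    return(igraph::graph_from_data_frame(df, directed = directed, vertices = verts))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  igraph::graph_from_data_frame(df, directed = directed)
}

# sort vertices (lexicographic) and edges (from, to)
canonical_graph <- function(graph) {
  if (is.null(igraph::V(graph)$name)) {
    igraph::V(graph)$name <- as.character(seq_len(igraph::vcount(graph)))
  }
  perm <- order(igraph::V(graph)$name)
  igraph::permute(graph, order(perm))
}

edge_tibble <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  df <- tibble::tibble(from = el[, 1], to = el[, 2])
  eattr <- igraph::edge_attr(graph)
  for (a in names(eattr)) df[[a]] <- eattr[[a]]
  dplyr::arrange(df, .data$from, .data$to)
}
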