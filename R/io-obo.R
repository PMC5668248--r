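# A deliberately small OBO reader: [Term] stanzas with id, name, namespace
# and is_a only (other tags are ignored). Enough to carry a GO DAG subset
# for the node-score network.

#' Read a GO DAG from a lite OBO file
#'
#' Supports `[Term]` stanzas with `id`, `name`, `namespace` and `is_a`
#' tags; every other tag is ignored. The child-to-parent `is_a` edges must
#' form a directed acyclic graph; a cycle is a structural error and is
#' reported with the terms involved. `is_a` references to undeclared terms
#' are errors.
#'
#' @param path Path to an OBO file.
#' @return A `mir_go_dag`: list with `terms` (tibble `id`, `name`,
#'   `namespace`) and `edges` (tibble `child`, `parent`).
#' @export
read_obo_lite <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  terms <- list()
  edges <- list()
  cur <- NULL
  in_term <- FALSE
  flush_term <- function(cur) {
    if (is.null(cur$id)) abort("OBO [Term] stanza without an id tag")
    cur
  }
  store <- function(cur) {
    terms[[length(terms) + 1L]] <<- tibble::tibble(
      id = cur$id,
      name = cur$name %||% cur$id,
      namespace = normalize_namespace(cur$namespace %||% "BP")
    )
    for (p in cur$parents) {
      edges[[length(edges) + 1L]] <<- tibble::tibble(child = cur$id, parent = p)
    }
  }
  for (raw in lines) {
    line <- stringr::str_trim(sub("!.*$", "", raw))
    if (line == "") next
    if (startsWith(line, "[")) {
      if (in_term && !is.null(cur)) store(flush_term(cur))
      in_term <- identical(line, "[Term]")
      cur <- list(parents = character(0))
      next
    }
    if (!in_term) next
    kv <- stringr::str_match(line, "^([A-Za-z_]+):\\s*(.*)$")
    if (is.na(kv[1, 1])) next
    key <- kv[1, 2]
    val <- stringr::str_trim(kv[1, 3])
    if (key == "id") {
      cur$id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "namespace") {
      cur$namespace <- val
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, stringr::str_extract(val, "^\\S+"))
    }
    # other tags ignored by design
  }
  if (in_term && !is.null(cur)) store(flush_term(cur))
  terms <- if (length(terms)) dplyr::bind_rows(terms) else {
    tibble::tibble(id = character(), name = character(), namespace = character())
  }
  edges <- if (length(edges)) dplyr::distinct(dplyr::bind_rows(edges)) else {
    tibble::tibble(child = character(), parent = character())
  }
  new_go_dag(terms, edges)
}

normalize_namespace <- function(x) {
  dplyr::case_when(
    x %in% c("biological_process", "BP") ~ "BP",
    x %in% c("molecular_function", "MF") ~ "MF",
    x %in% c("cellular_component", "CC") ~ "CC",
    TRUE ~ x
  )
}

# constructor + validation (acyclicity, declared parents)
new_go_dag <- function(terms, edges) {
  if (anyDuplicated(terms$id)) abort("duplicate GO term ids")
  missing <- setdiff(edges$parent, terms$id)
  if (length(missing) > 0L) {
    abort(paste0(
      "is_a references undeclared term(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  dag <- structure(list(terms = terms, edges = edges), class = "mir_go_dag")
  g <- go_dag_graph(dag)
  if (igraph::vcount(g) > 0L && !igraph::is_dag(g)) {
    cyc <- find_cycle_terms(g)
    abort(paste0(
      "GO is_a edges contain a directed cycle: ",
      paste(cyc, collapse = " -> ")
    ))
  }
  dag
}

# igraph view, edges child -> parent
go_dag_graph <- function(dag) {
  igraph::graph_from_data_frame(
    dag$edges,
    directed = TRUE,
    vertices = dag$terms$id
  )
}

find_cycle_terms <- function(g) {
  # peel vertices with no outgoing edges until only cycle members remain
  repeat {
    sinks <- which(igraph::degree(g, mode = "out") == 0L)
    if (length(sinks) == 0L || igraph::vcount(g) == 0L) break
    g <- igraph::delete_vertices(g, sinks)
  }
  igraph::V(g)$name
}

#' @export
print.mir_go_dag <- function(x, ...) {
  cat("<mir_go_dag> ", nrow(x$terms), " terms, ", nrow(x$edges),
    " is_a edges\n",
    sep = ""
  )
  invisible(x)
}

#' Write a GO DAG as a lite OBO file
#'
#' @param dag A `mir_go_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo_lite <- function(dag, path) {
  stopifnot(inherits(dag, "mir_go_dag"))
  ns_long <- c(
    BP = "biological_process", MF = "molecular_function",
    CC = "cellular_component"
  )
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  writeLines("format-version: 1.2", con)
  for (r in seq_len(nrow(dag$terms))) {
    writeLines("", con)
    writeLines("[Term]", con)
    writeLines(paste0("id: ", dag$terms$id[r]), con)
    writeLines(paste0("name: ", dag$terms$name[r]), con)
    ns <- dag$terms$namespace[r]
    if (ns %in% names(ns_long)) ns <- ns_long[[ns]]
    writeLines(paste0("namespace: ", ns), con)
    parents <- dag$edges$parent[dag$edges$child == dag$terms$id[r]]
    for (p in parents) writeLines(paste0("is_a: ", p), con)
  }
  invisible(path)
}
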