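# Interaction matrices, bipartite miRNA-target networks, condition
# comparison, and degree / correlation profiling.

#' Build a binary miRNA-target interaction matrix
#'
#' `A[i, j] = 1` iff the (miRNA i, target j) pair occurs in the input
#' list, else 0; rows and columns are the sorted unique labels.
#'
#' @param pairs Data frame whose first two columns are miRNA and target
#'   labels (extra columns ignored), or a tibble with `mirna` and `target`
#'   columns.
#' @return Integer 0/1 matrix with miRNAs as rows, targets as columns.
#' @export
#' @examples
#' build_adjacency(data.frame(mirna = "m1", target = c("t1", "t2")))
build_adjacency <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (!all(c("mirna", "target") %in% names(pairs))) {
    names(pairs)[1:2] <- c("mirna", "target")
  }
  mirnas <- sort(unique(pairs$mirna))
  targets <- sort(unique(pairs$target))
  A <- matrix(0L, length(mirnas), length(targets),
    dimnames = list(mirnas, targets)
  )
  if (nrow(pairs) > 0L) {
    A[cbind(pairs$mirna, pairs$target)] <- 1L
  }
  A
}

#' Build a directed bipartite miRNA-target network
#'
#' Nodes split into the miRNA set and the target set; a directed edge
#' miRNA -> target exists wherever the interaction matrix is 1. Labels
#' with no interactions are excluded.
#'
#' @param x An interaction matrix from [build_adjacency()] or a pair
#'   data frame (passed through [build_adjacency()]).
#' @param condition Optional condition label stored on the network.
#' @return A `mir_bipartite`: list with `graph` (igraph, node attribute
#'   `side` in mirna/target), `condition`.
#' @export
build_bipartite <- function(x, condition = NA_character_) {
  A <- if (is.matrix(x)) x else build_adjacency(x)
  hit <- which(A == 1L, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = rownames(A)[hit[, 1]],
    to = colnames(A)[hit[, 2]]
  )
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  mirnas <- sort(unique(edges$from))
  targets <- sort(unique(edges$to))
  if (length(intersect(mirnas, targets)) > 0L) {
    abort("a label occurs on both sides of the bipartite network")
  }
  g <- igraph::graph_from_data_frame(
    edges,
    directed = TRUE,
    vertices = tibble::tibble(
      name = c(mirnas, targets),
      side = c(
        rep("mirna", length(mirnas)),
        rep("target", length(targets))
      )
    )
  )
  structure(
    list(graph = g, condition = condition),
    class = "mir_bipartite"
  )
}

#' @export
print.mir_bipartite <- function(x, ...) {
  side <- igraph::V(x$graph)$side
  cat("<mir_bipartite>",
    if (!is.na(x$condition)) paste0("[", x$condition, "]") else "",
    sum(side == "mirna"), "miRNAs,", sum(side == "target"), "targets,",
    igraph::ecount(x$graph), "edges\n"
  )
  invisible(x)
}

#' Compare miRNA-target inventories of two conditions
#'
#' Splits miRNA families and targets into common and condition-unique
#' sets and calls regulation for every shared target: `up` iff the second
#' condition's FPKM exceeds the first, `down` iff smaller, `unchanged`
#' iff equal. Shared targets lacking an FPKM value on either side are
#' reported with regulation `unknown` and a warning.
#'
#' @param targets_a,targets_b Per-condition target tables: tibbles with
#'   `mirna`, `target`, `fpkm` (and optionally `target_key`, a normalized
#'   matching key; computed when absent).
#' @param condition_a,condition_b Condition labels (defaults `"A"`,
#'   `"B"`, or taken from a `condition` column when present).
#' @return A `mir_condition_comparison`: list with `common_mirnas`,
#'   `unique_mirnas_a`, `unique_mirnas_b`, `common_targets` (tibble with
#'   `fpkm_a`, `fpkm_b`, `regulation`), `unique_targets_a`,
#'   `unique_targets_b`, and the condition labels.
#' @export
compare_conditions <- function(targets_a, targets_b,
                               condition_a = NULL, condition_b = NULL) {
  prep <- function(x, default_label) {
    x <- tibble::as_tibble(x)
    stopifnot(all(c("mirna", "target") %in% names(x)))
    if (!"fpkm" %in% names(x)) x$fpkm <- NA_real_
    if (!"target_key" %in% names(x)) {
      x$target_key <- normalize_target_name(x$target)
    }
    label <- if ("condition" %in% names(x) && nrow(x) > 0L) {
      x$condition[1]
    } else {
      default_label
    }
    list(tbl = x, label = label)
  }
  a <- prep(targets_a, "A")
  b <- prep(targets_b, "B")
  condition_a <- condition_a %||% a$label
  condition_b <- condition_b %||% b$label

  fams_a <- sort(unique(mirna_family(a$tbl$mirna)))
  fams_b <- sort(unique(mirna_family(b$tbl$mirna)))
  keys_a <- unique(a$tbl$target_key)
  keys_b <- unique(b$tbl$target_key)
  common_keys <- intersect(keys_a, keys_b)

  fpkm_of <- function(tbl, keys) {
    dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(tbl, .data$target_key %in% keys),
        .data$target_key
      ),
      target = .data$target[1],
      mirnas = paste(sort(unique(mirna_family(.data$mirna))), collapse = ";"),
      fpkm = .data$fpkm[1],
      .groups = "drop"
    )
  }
  ca <- fpkm_of(a$tbl, common_keys)
  cb <- fpkm_of(b$tbl, common_keys)
  common <- dplyr::full_join(
    dplyr::rename(ca, target_a = "target", mirnas_a = "mirnas", fpkm_a = "fpkm"),
    dplyr::rename(cb, target_b = "target", mirnas_b = "mirnas", fpkm_b = "fpkm"),
    by = "target_key"
  )
  common$regulation <- ifelse(
    is.na(common$fpkm_a) | is.na(common$fpkm_b),
    "unknown",
    regulation_call(common$fpkm_a, common$fpkm_b)
  )
  if (any(common$regulation == "unknown")) {
    warn(paste0(
      sum(common$regulation == "unknown"),
      " shared target(s) lack expression on one side; regulation unknown"
    ))
  }
  common <- dplyr::arrange(common, .data$target_key)
  structure(
    list(
      condition_a = condition_a, condition_b = condition_b,
      common_mirnas = intersect(fams_a, fams_b),
      unique_mirnas_a = setdiff(fams_a, fams_b),
      unique_mirnas_b = setdiff(fams_b, fams_a),
      common_targets = common,
      unique_targets_a = dplyr::filter(a$tbl, !.data$target_key %in% common_keys),
      unique_targets_b = dplyr::filter(b$tbl, !.data$target_key %in% common_keys),
      targets_a = a$tbl, targets_b = b$tbl
    ),
    class = "mir_condition_comparison"
  )
}

#' @export
print.mir_condition_comparison <- function(x, ...) {
  cat("<mir_condition_comparison> ", x$condition_a, " vs ", x$condition_b,
    "\n  common miRNA families: ", length(x$common_mirnas),
    "\n  unique to ", x$condition_a, ": ", length(x$unique_mirnas_a),
    "; unique to ", x$condition_b, ": ", length(x$unique_mirnas_b),
    "\n  shared targets: ", nrow(x$common_targets), "\n",
    sep = ""
  )
  invisible(x)
}

#' Degree and degree-distribution profile of a network
#'
#' Degrees are computed on the undirected view of the graph; `p(k)` is
#' the fraction of nodes with degree `k` and sums to 1.
#'
#' @param network An igraph object or a `mir_bipartite` /
#'   `mir_coexpr_network`.
#' @return A `mir_degree_profile`: list with `degrees` (tibble `node`,
#'   `side` if available, `degree`) and `distribution` (tibble `k`,
#'   `count`, `p`).
#' @export
degree_profile <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0L) {
    return(structure(
      list(
        degrees = tibble::tibble(
          node = character(), degree = integer()
        ),
        distribution = tibble::tibble(
          k = integer(), count = integer(), p = double()
        )
      ),
      class = "mir_degree_profile"
    ))
  }
  deg <- igraph::degree(g, mode = "all")
  node_names <- igraph::V(g)$name %||% as.character(seq_along(deg))
  degrees <- tibble::tibble(node = node_names, degree = as.integer(deg))
  if (!is.null(igraph::V(g)$side)) degrees$side <- igraph::V(g)$side
  dist <- dplyr::count(degrees, k = .data$degree, name = "count")
  dist$p <- dist$count / sum(dist$count)
  structure(
    list(degrees = dplyr::arrange(degrees, .data$node), distribution = dist),
    class = "mir_degree_profile"
  )
}

#' @export
print.mir_degree_profile <- function(x, ...) {
  cat("<mir_degree_profile>", nrow(x$degrees), "nodes\n")
  print(x$distribution)
  invisible(x)
}

#' Degree correlation (assortativity) of a network
#'
#' Pearson-type correlation of the endpoint degrees over all connexions:
#' each undirected edge contributes its endpoint-degree pair (j, k)
#' symmetrized, and
#' \deqn{r = \frac{M^{-1}\sum_i j_i k_i - [M^{-1}\sum_i \frac12 (j_i + k_i)]^2}{M^{-1}\sum_i \frac12 (j_i^2 + k_i^2) - [M^{-1}\sum_i \frac12 (j_i + k_i)]^2}}
#' with M the number of connexions. Degrees are taken on the undirected
#' view. When the denominator vanishes (all degrees equal) `r` is
#' undefined and returned as `NA` with a diagnostic message.
#'
#' @param network An igraph object or wrapper; must have at least 1 edge.
#' @return A `mir_degree_correlation`: list with `r`, `m` (edge count)
#'   and `pairs` (tibble of endpoint degrees `j`, `k` per edge).
#' @export
degree_correlation <- function(network) {
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0L) abort("degree correlation needs at least one edge")
  gu <- igraph::as_undirected(g, mode = "collapse")
  deg <- igraph::degree(gu)
  el <- igraph::as_edgelist(gu, names = FALSE)
  j <- deg[el[, 1]]
  k <- deg[el[, 2]]
  m <- nrow(el)
  # symmetrized sums (each edge contributes (j,k) and (k,j))
  sum_jk <- mean(j * k)
  sum_mean <- mean((j + k) / 2)
  sum_sq <- mean((j^2 + k^2) / 2)
  denom <- sum_sq - sum_mean^2
  r <- if (abs(denom) < 1e-12) {
    inform("degree correlation undefined: zero variance in endpoint degrees")
    NA_real_
  } else {
    (sum_jk - sum_mean^2) / denom
  }
  structure(
    list(
      r = r, m = m,
      pairs = tibble::tibble(j = as.integer(j), k = as.integer(k))
    ),
    class = "mir_degree_correlation"
  )
}

#' @export
print.mir_degree_correlation <- function(x, ...) {
  cat("<mir_degree_correlation> r =",
    if (is.na(x$r)) "undefined" else sprintf("%.4f", x$r),
    "over", x$m, "connexions\n"
  )
  invisible(x)
}

as_igraph <- function(network) {
  if (igraph::is_igraph(network)) return(network)
  if (is.list(network) && igraph::is_igraph(network$graph)) {
    return(network$graph)
  }
  abort("not a network object")
}

#' Pearson correlation of expression between two conditions
#'
#' Two modes. `mode = "replicate"` (per-transcript): correlation between
#' the two conditions' replicate FPKM vectors for one transcript
#' (replicates matched by index; needs at least 3 replicates per
#' condition). `mode = "profile"` (cross-transcript): correlation between
#' the two conditions' mean-FPKM vectors over a transcript set.
#'
#' @param expression A long expression table (see
#'   [as_expression_table()]).
#' @param transcript_id Transcript for `"replicate"` mode, or a vector of
#'   transcripts for `"profile"` mode (default: all).
#' @param condition_a,condition_b The two condition labels.
#' @param mode `"replicate"` or `"profile"`.
#' @return Pearson r in `[-1, 1]`, or `NA` (with a diagnostic) when a
#'   vector has zero variance.
#' @export
expression_pcc <- function(expression, transcript_id = NULL,
                           condition_a, condition_b,
                           mode = c("replicate", "profile")) {
  mode <- match.arg(mode)
  expression <- as_expression_table(expression)
  if (mode == "replicate") {
    if (is.null(transcript_id) || length(transcript_id) != 1L) {
      abort("replicate mode needs exactly one transcript_id")
    }
    sub <- dplyr::filter(expression, .data$transcript_id == !!transcript_id)
    va <- dplyr::arrange(
      dplyr::filter(sub, .data$condition == condition_a), .data$replicate
    )
    vb <- dplyr::arrange(
      dplyr::filter(sub, .data$condition == condition_b), .data$replicate
    )
    if (nrow(va) < 3L || nrow(vb) < 3L) {
      abort(paste0(
        "fewer than 3 replicates for ", transcript_id,
        "; use mode = \"profile\" for single-value-per-condition data"
      ))
    }
    if (nrow(va) != nrow(vb)) abort("unequal replicate counts between conditions")
    x <- va$fpkm
    y <- vb$fpkm
  } else {
    ids <- transcript_id %||% sort(unique(expression$transcript_id))
    means <- dplyr::summarise(
      dplyr::group_by(
        dplyr::filter(
          expression,
          .data$transcript_id %in% ids,
          .data$condition %in% c(condition_a, condition_b)
        ),
        .data$transcript_id, .data$condition
      ),
      fpkm = mean(.data$fpkm), .groups = "drop"
    )
    wide <- tidyr::pivot_wider(
      means,
      names_from = "condition", values_from = "fpkm"
    )
    if (!all(c(condition_a, condition_b) %in% names(wide))) {
      abort("both conditions must be present in the expression table")
    }
    x <- wide[[condition_a]]
    y <- wide[[condition_b]]
    if (length(x) < 3L) abort("profile mode needs at least 3 transcripts")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    inform("PCC undefined: zero variance in an FPKM vector")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Select the query genes for co-expression analysis
#'
#' Restricts to transcripts targeted by miRNAs in both conditions and
#' applies a selection rule: `"packaged"` uses the curated gene-symbol
#' list shipped with the package (our transcription of the published
#' selection, which no numeric FPKM rule reproduces; see the methods
#' vignette), `"both_conditions"` keeps shared targets quantified in both
#' conditions, `"all"` keeps every shared target.
#'
#' @param comparison A `mir_condition_comparison`.
#' @param rule `"packaged"`, `"both_conditions"` or `"all"`.
#' @param fixtures Fixture tables (for the synonym map; default loaded).
#' @return Tibble with `gene` (symbol where known, else target name),
#'   `target_key`, `mirnas`, ordered deterministically.
#' @export
select_pcc_genes <- function(comparison,
                             rule = c("packaged", "both_conditions", "all"),
                             fixtures = load_fixture_tables()) {
  rule <- match.arg(rule)
  ct <- comparison$common_targets
  syn <- fixtures$synonyms
  syn$target_key <- normalize_target_name(syn$target_name)
  if (rule == "packaged") {
    # curated list, applied over every target of the miRNA families found
    # in both conditions (some published selections are quantified in one
    # condition only; see the methods vignette)
    pool <- dplyr::bind_rows(comparison$targets_a, comparison$targets_b)
    pool$family <- mirna_family(pool$mirna)
    pool <- dplyr::filter(pool, .data$family %in% comparison$common_mirnas)
    keep <- dplyr::semi_join(syn, pool, by = "target_key")
    mirnas <- vapply(keep$target_key, function(k) {
      paste(sort(unique(pool$family[pool$target_key == k])), collapse = ";")
    }, character(1))
    return(tibble::tibble(
      gene = keep$symbol,
      target_key = keep$target_key,
      mirnas = unname(mirnas)
    ))
  }
  if (rule == "both_conditions") {
    ct <- dplyr::filter(ct, !is.na(.data$fpkm_a) & !is.na(.data$fpkm_b))
  }
  out <- dplyr::left_join(ct, syn, by = "target_key")
  tibble::tibble(
    gene = dplyr::coalesce(out$symbol, out$target_a, out$target_b),
    target_key = out$target_key,
    mirnas = combine_mirna_labels(out$mirnas_a, out$mirnas_b)
  )
}

combine_mirna_labels <- function(a, b) {
  purrr::map2_chr(a, b, function(x, y) {
    fams <- unique(c(
      if (!is.na(x)) strsplit(x, ";")[[1]] else character(0),
      if (!is.na(y)) strsplit(y, ";")[[1]] else character(0)
    ))
    paste(sort(fams), collapse = ";")
  })
}
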