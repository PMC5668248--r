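# Independent oracles used across the suite. These share the model
# *constants* with the package (they define the model) but never its
# algorithms: folding is checked by exhaustive enumeration over all nested
# structures, duplex scoring by a gap-capped alignment DP, degree
# correlation by a direct Pearson correlation of symmetrized endpoint
# degrees, and GO subtree totals by graph reachability.

RNA5 <- c("A", "C", "G", "U", "N")

oracle_codes <- function(sequence) {
  match(strsplit(toupper(sequence), "")[[1]], RNA5) - 1L
}

# pair-type table matching the model convention:
# 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG, -1 none (rows/cols A C G U N)
oracle_pt <- matrix(-1L, 5, 5)
oracle_pt[1, 4] <- 0L
oracle_pt[4, 1] <- 1L
oracle_pt[2, 3] <- 2L
oracle_pt[3, 2] <- 3L
oracle_pt[3, 4] <- 4L
oracle_pt[4, 3] <- 5L

# all nested pair sets on 1..n with hairpin loops >= minh, as 2-row
# matrices (open; close); positions only, so one enumeration serves every
# sequence of that length
enum_nested_pairsets <- function(n, minh = 3L) {
  rec <- function(i, j) {
    if (j - i < minh + 1L) {
      return(list(matrix(integer(0), nrow = 2)))
    }
    out <- rec(i + 1L, j)
    for (k in seq(i + minh + 1L, j)) {
      inner <- rec(i + 1L, k - 1L)
      right <- rec(k + 1L, j)
      for (A in inner) {
        for (B in right) {
          out[[length(out) + 1L]] <- cbind(c(i, k), A, B)
        }
      }
    }
    out
  }
  if (n < minh + 2L) {
    return(list(matrix(integer(0), nrow = 2)))
  }
  rec(1L, n)
}

# position-only annotation of a pair set: loop penalties and the list of
# stacked (outer, inner) pair column indices
annotate_pairset <- function(pairs, hairpin_penalty = 3, loop_penalty = 2) {
  k <- ncol(pairs)
  if (k == 0L) {
    return(list(pairs = pairs, penalty = 0, stacks = matrix(integer(0), 2)))
  }
  ord <- order(pairs[1, ])
  pairs <- pairs[, ord, drop = FALSE]
  parent <- rep(NA_integer_, k)
  for (c1 in seq_len(k)) {
    best <- NA_integer_
    for (c2 in seq_len(k)) {
      if (c2 == c1) next
      if (pairs[1, c2] < pairs[1, c1] && pairs[2, c2] > pairs[2, c1]) {
        if (is.na(best) || pairs[1, c2] > pairs[1, best]) best <- c2
      }
    }
    parent[c1] <- best
  }
  children <- lapply(seq_len(k), function(c1) which(parent == c1))
  penalty <- 0
  stacks <- list()
  for (c1 in seq_len(k)) {
    ch <- children[[c1]]
    if (length(ch) == 0L) {
      penalty <- penalty + hairpin_penalty
    } else if (length(ch) == 1L) {
      stacked <- pairs[1, ch] == pairs[1, c1] + 1L &&
        pairs[2, ch] == pairs[2, c1] - 1L
      if (stacked) {
        stacks[[length(stacks) + 1L]] <- c(c1, ch)
      } else {
        penalty <- penalty + loop_penalty
      }
    }
    # >= 2 children: multiloop, free under the model
  }
  stacks <- if (length(stacks)) {
    matrix(unlist(stacks), nrow = 2)
  } else {
    matrix(integer(0), 2)
  }
  list(pairs = pairs, penalty = penalty, stacks = stacks)
}

# annotated structure sets, cached per length
oracle_struct_cache <- new.env(parent = emptyenv())
oracle_structs <- function(n, params = fold_energy_params()) {
  key <- as.character(n)
  if (!is.null(oracle_struct_cache[[key]])) {
    return(oracle_struct_cache[[key]])
  }
  st <- lapply(
    enum_nested_pairsets(n, params$min_hairpin),
    annotate_pairset,
    hairpin_penalty = params$hairpin_penalty,
    loop_penalty = params$loop_penalty
  )
  oracle_struct_cache[[key]] <- st
  st
}

# enumeration MFE (ties toward fewer pairs), fully independent of the DP
oracle_fold_mfe <- function(sequence, params = fold_energy_params()) {
  codes <- oracle_codes(sequence)
  structs <- oracle_structs(length(codes), params)
  best_e <- 0
  best_p <- 0L
  for (st in structs) {
    k <- ncol(st$pairs)
    if (k == 0L) next
    pts <- oracle_pt[cbind(
      codes[st$pairs[1, ]] + 1L, codes[st$pairs[2, ]] + 1L
    )]
    if (any(pts < 0L)) next
    e <- st$penalty
    if (ncol(st$stacks) > 0L) {
      for (s in seq_len(ncol(st$stacks))) {
        po <- pts[st$stacks[1, s]]
        pi <- pts[st$stacks[2, s]]
        e <- e + if (po >= 4L || pi >= 4L) {
          params$gu_stack
        } else {
          params$stack_table[po + 1L, pi + 1L]
        }
      }
    }
    if (e < best_e - 1e-9 || (abs(e - best_e) <= 1e-9 && k < best_p)) {
      best_e <- e
      best_p <- k
    }
  }
  list(mfe = best_e, n_pairs = best_p)
}

# gap-capped global alignment DP over the duplex scoring scheme: an
# independent minimizer over all alignments with <= max_gaps gaps
oracle_duplex_expectation <- function(mirna, site, scheme = duplex_scheme()) {
  U <- min(scheme$upsize, nchar(mirna))
  m <- oracle_codes(substr(mirna, 1, U)) + 1L
  svec <- rev(oracle_codes(site) + 1L)
  S <- length(svec)
  pen <- matrix(scheme$mismatch, 5, 5)
  pen[1, 4] <- pen[4, 1] <- pen[2, 3] <- pen[3, 2] <- scheme$match
  pen[3, 4] <- pen[4, 3] <- scheme$wobble
  dbl <- ifelse(
    scheme$core_double & seq_len(U) >= scheme$core[1] &
      seq_len(U) <= scheme$core[2], 2, 1
  )
  gap_at <- scheme$gap * dbl
  # D[k+1, s+1, g+1]: k miRNA and s site elements consumed, g gaps used
  D <- array(Inf, dim = c(U + 1L, S + 1L, scheme$max_gaps + 1L))
  D[1, 1, 1] <- 0
  for (k in 0:U) {
    for (s in 0:S) {
      for (g in 0:scheme$max_gaps) {
        v <- D[k + 1L, s + 1L, g + 1L]
        if (!is.finite(v)) next
        if (k < U && s < S) {
          cost <- pen[m[k + 1L], svec[s + 1L]] * dbl[k + 1L]
          D[k + 2L, s + 2L, g + 1L] <-
            min(D[k + 2L, s + 2L, g + 1L], v + cost)
        }
        if (g < scheme$max_gaps) {
          if (k < U) { # miRNA base unopposed (deletion in target)
            D[k + 2L, s + 1L, g + 2L] <-
              min(D[k + 2L, s + 1L, g + 2L], v + gap_at[k + 1L])
          }
          if (s < S) { # extra target base bulged out
            D[k + 1L, s + 2L, g + 2L] <-
              min(D[k + 1L, s + 2L, g + 2L], v + gap_at[min(s + 1L, U)])
          }
        }
      }
    }
  }
  min(D[U + 1L, S + 1L, ])
}

# Newman-style degree assortativity via plain Pearson correlation of the
# symmetrized endpoint-degree list
oracle_assortativity <- function(graph) {
  gu <- igraph::as_undirected(graph, mode = "collapse")
  deg <- igraph::degree(gu)
  el <- igraph::as_edgelist(gu, names = FALSE)
  j <- deg[el[, 1]]
  k <- deg[el[, 2]]
  suppressWarnings(stats::cor(c(j, k), c(k, j)))
}

# subtree annotation total via graph reachability (alpha = 1 oracle)
oracle_subtree_total <- function(dag, term, counts) {
  g <- igraph::graph_from_data_frame(
    dag$edges,
    directed = TRUE, vertices = dag$terms$id
  )
  desc <- names(igraph::subcomponent(g, term, mode = "in"))
  sum(counts[names(counts) %in% desc])
}

# small sequence-table builders
seq_tbl <- function(...) {
  x <- c(...)
  tibble::tibble(id = names(x), sequence = unname(x))
}

random_seq <- function(n, letters = c("A", "C", "G", "U")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
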