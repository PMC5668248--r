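# RNA secondary-structure prediction under a simplified nearest-neighbour
# model, plus hairpin geometry used by the precursor criteria.

#' Energy parameters of the built-in folding model
#'
#' The model scores a nested secondary structure as the sum of stacking
#' terms for directly adjacent base pairs plus flat loop penalties. The
#' stacking table has 16 entries, indexed by the Watson-Crick type of the
#' outer and inner pair (AU, UA, CG, GC); any stack involving a G:U pair
#' contributes the single `gu_stack` term instead. Hairpin loops cost
#' `hairpin_penalty`, bulge/internal loops `loop_penalty` each; multiloops
#' and exterior bases are free. Units are kcal/mol.
#'
#' @param stack_table 4x4 numeric matrix of stacking energies
#'   (rows = outer pair, cols = inner pair, order AU, UA, CG, GC).
#' @param gu_stack Stacking term for any stack involving a G:U pair.
#' @param hairpin_penalty Penalty per hairpin loop.
#' @param loop_penalty Penalty per bulge or internal loop.
#' @param min_hairpin Minimum number of unpaired bases in a hairpin loop.
#' @param max_loop Maximum total unpaired length of a bulge/internal loop.
#' @return A list of model parameters, class `mir_fold_params`.
#' @export
#' @examples
#' fold_energy_params()$stack_table
fold_energy_params <- function(stack_table = NULL, gu_stack = -0.5,
                               hairpin_penalty = 3.0, loop_penalty = 2.0,
                               min_hairpin = 3L, max_loop = 30L) {
  if (is.null(stack_table)) {
    stack_table <- matrix(
      c(
        -0.9, -0.9, -2.1, -2.4, # outer AU
        -0.9, -0.9, -2.1, -2.1, # outer UA
        -2.1, -2.1, -3.3, -2.4, # outer CG
        -2.4, -2.1, -3.4, -3.3  # outer GC
      ),
      nrow = 4, byrow = TRUE,
      dimnames = list(
        outer = c("AU", "UA", "CG", "GC"),
        inner = c("AU", "UA", "CG", "GC")
      )
    )
  }
  stopifnot(is.matrix(stack_table), all(dim(stack_table) == c(4, 4)))
  structure(
    list(
      stack_table = stack_table, gu_stack = gu_stack,
      hairpin_penalty = hairpin_penalty, loop_penalty = loop_penalty,
      min_hairpin = as.integer(min_hairpin), max_loop = as.integer(max_loop)
    ),
    class = "mir_fold_params"
  )
}

#' Fold an RNA sequence to its minimum-free-energy structure
#'
#' Computes the minimum-energy nested structure of a single RNA under the
#' built-in model (see [fold_energy_params()]): Watson-Crick and G:U pairs,
#' stacking energies for adjacent pairs, flat hairpin and bulge/internal
#' loop penalties, hairpin loops of at least three unpaired bases, no
#' pseudoknots. Ties are broken toward fewer pairs, then by a fixed
#' deterministic traceback order, so output is reproducible.
#'
#' An external thermodynamic folder can be plugged in via `backend`:
#' either a function `function(sequence) list(structure=, mfe=)` or a
#' command template (a string containing `{input}` or reading stdin) whose
#' stdout follows the ViennaRNA `RNAfold` convention, i.e. the last line
#' is `<dot-bracket> (<energy>)`.
#'
#' @param sequence A single RNA (or DNA; T is converted to U) string.
#' @param params Energy model from [fold_energy_params()].
#' @param backend `"builtin"` (default), a function, or a command string.
#' @return An object of class `mir_fold`: list with `sequence`,
#'   `structure` (dot-bracket), `mfe` (kcal/mol), `pair_table` (1-based
#'   partner index per position, 0 = unpaired) and `n_pairs`.
#' @export
#' @examples
#' fold_rna("GGGGGAAAACCCCC")
fold_rna <- function(sequence,
                     params = fold_energy_params(),
                     backend = getOption("mirframe.fold_backend", "builtin")) {
  stopifnot(length(sequence) == 1L)
  sequence <- as_rna(sequence)
  if (nchar(sequence) < 1L) abort("sequence must have length >= 1")

  if (is.function(backend)) {
    res <- backend(sequence)
    return(new_mir_fold(sequence, res$structure, res$mfe))
  }
  if (is.character(backend) && !identical(backend, "builtin")) {
    res <- fold_via_command(sequence, backend)
    return(new_mir_fold(sequence, res$structure, res$mfe))
  }

  codes <- encode_rna(sequence)
  out <- .fold_engine(
    codes, params$stack_table, params$gu_stack,
    params$hairpin_penalty, params$loop_penalty,
    params$min_hairpin, params$max_loop
  )
  structure(
    list(
      sequence = sequence, structure = out$structure, mfe = out$mfe,
      pair_table = out$pair_table, n_pairs = out$n_pairs
    ),
    class = "mir_fold"
  )
}

# run an external folding command (RNAfold-compatible stdout contract)
fold_via_command <- function(sequence, command) {
  input <- tempfile(fileext = ".fa")
  on.exit(unlink(input), add = TRUE)
  writeLines(sequence, input)
  cmd <- if (grepl("{input}", command, fixed = TRUE)) {
    gsub("{input}", shQuote(input), command, fixed = TRUE)
  } else {
    paste(command, "<", shQuote(input))
  }
  out <- suppressWarnings(system(cmd, intern = TRUE))
  if (length(out) == 0L) abort("fold backend command produced no output")
  line <- out[length(out)]
  m <- stringr::str_match(line, "^([.()]+)\\s+\\(\\s*(-?\\d+(?:\\.\\d+)?)\\)")
  if (is.na(m[1, 1])) {
    abort(paste0("cannot parse fold backend output line: ", line))
  }
  list(structure = m[1, 2], mfe = as.numeric(m[1, 3]))
}

# build a mir_fold from a dot-bracket string (external backends)
new_mir_fold <- function(sequence, db, mfe) {
  n <- nchar(sequence)
  if (nchar(db) != n) abort("backend structure length != sequence length")
  pt <- pair_table_from_dotbracket(db)
  structure(
    list(
      sequence = sequence, structure = db, mfe = as.numeric(mfe),
      pair_table = pt, n_pairs = sum(pt > 0) %/% 2L
    ),
    class = "mir_fold"
  )
}

pair_table_from_dotbracket <- function(db) {
  v <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(v)
  pt <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (v[i] == "(") {
      stack <- c(stack, i)
    } else if (v[i] == ")") {
      if (length(stack) == 0L) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    } else if (v[i] != ".") {
      abort("dot-bracket string may only contain '.', '(' and ')'")
    }
  }
  if (length(stack) > 0L) abort("unbalanced dot-bracket string")
  pt
}

#' @export
print.mir_fold <- function(x, ...) {
  cat("<mir_fold> ", nchar(x$sequence), " nt, ", x$n_pairs, " pairs, MFE ",
    sprintf("%.2f", x$mfe), " kcal/mol\n",
    sep = ""
  )
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

# --- hairpin geometry ------------------------------------------------------

# Pair tree: for each pair (i, j), its parent is the smallest enclosing pair.
# Returns tibble(i, j, parent (row index or NA), n_children).
pair_tree <- function(pair_table) {
  opens <- which(pair_table > seq_along(pair_table))
  if (length(opens) == 0L) {
    return(tibble::tibble(
      i = integer(), j = integer(),
      parent = integer(), n_children = integer()
    ))
  }
  pairs <- tibble::tibble(i = opens, j = pair_table[opens])
  pairs <- dplyr::arrange(pairs, .data$i)
  parent <- rep(NA_integer_, nrow(pairs))
  stack <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    while (length(stack) > 0L && pairs$j[stack[length(stack)]] < pairs$i[r]) {
      stack <- stack[-length(stack)]
    }
    if (length(stack) > 0L) parent[r] <- stack[length(stack)]
    stack <- c(stack, r)
  }
  n_children <- tabulate(parent[!is.na(parent)], nbins = nrow(pairs))
  pairs$parent <- parent
  pairs$n_children <- n_children
  pairs
}

# The maximal stem: for every hairpin loop (pair with no children), walk
# outward while each ancestor has exactly one child; the longest such chain
# (ties: leftmost loop) is the reference stem. Returns NULL if no pairs.
maximal_stem <- function(fold) {
  tree <- pair_tree(fold$pair_table)
  if (nrow(tree) == 0L) return(NULL)
  hairpins <- which(tree$n_children == 0L)
  best <- NULL
  for (h in hairpins) {
    len <- 1L
    top <- h
    p <- tree$parent[h]
    while (!is.na(p) && tree$n_children[p] == 1L) {
      len <- len + 1L
      top <- p
      p <- tree$parent[p]
    }
    cand <- list(
      n_pairs = len,
      loop_start = tree$i[h], loop_end = tree$j[h],
      outer_start = tree$i[top], outer_end = tree$j[top]
    )
    if (is.null(best) ||
      cand$n_pairs > best$n_pairs ||
      (cand$n_pairs == best$n_pairs && cand$loop_start < best$loop_start)) {
      best <- cand
    }
  }
  best
}

#' Classify positions relative to the maximal hairpin stem
#'
#' Positions are classified against the terminal loop of the maximal stem
#' of the folded structure (the longest chain of pairs enclosing a single
#' terminal loop, leftmost on ties): `five_prime_arm` for positions between
#' the outermost stem pair and the loop on the 5' side, `three_prime_arm`
#' on the 3' side, `loop` strictly inside the terminal loop, and
#' `unpaired_tail` outside the stem (or everywhere if the structure has no
#' pairs).
#'
#' @param fold A `mir_fold` object.
#' @param positions 1-based positions (default: all).
#' @return Character vector of classifications, one per position.
#' @export
arm_of <- function(fold, positions = seq_len(nchar(fold$sequence))) {
  n <- nchar(fold$sequence)
  if (any(positions < 1L | positions > n)) {
    abort("positions must lie within the sequence")
  }
  stem <- maximal_stem(fold)
  if (is.null(stem)) {
    return(rep("unpaired_tail", length(positions)))
  }
  dplyr::case_when(
    positions > stem$loop_start & positions < stem$loop_end ~ "loop",
    positions >= stem$outer_start & positions <= stem$loop_start ~ "five_prime_arm",
    positions >= stem$loop_end & positions <= stem$outer_end ~ "three_prime_arm",
    TRUE ~ "unpaired_tail"
  )
}

#' Mismatches between a mature span and the opposite hairpin arm
#'
#' Counts mature positions that are unpaired, or whose pairing partner
#' falls outside the opposite arm of the maximal stem. Errors when the
#' span does not lie within a single arm (it crosses the terminal loop or
#' sits outside the hairpin), which corresponds to a violation of the
#' mature-in-one-arm precursor criterion.
#'
#' @param fold A `mir_fold` object.
#' @param start,end 1-based inclusive bounds of the mature span.
#' @return Integer mismatch count.
#' @export
duplex_mismatches <- function(fold, start, end) {
  stopifnot(start >= 1L, end >= start, end <= nchar(fold$sequence))
  span <- start:end
  arms <- arm_of(fold, span)
  if (!all(arms == "five_prime_arm") && !all(arms == "three_prime_arm")) {
    abort("mature span does not lie within a single hairpin arm")
  }
  stem <- maximal_stem(fold)
  opposite <- if (arms[1] == "five_prime_arm") {
    c(stem$loop_end, stem$outer_end)
  } else {
    c(stem$outer_start, stem$loop_start)
  }
  partners <- fold$pair_table[span]
  sum(partners == 0L | partners < opposite[1] | partners > opposite[2])
}
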