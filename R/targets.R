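# psRNATarget-style miRNA/mRNA duplex scoring: penalty sum ("expectation")
# over the first 20 miRNA positions, core-region doubling, at most one gap,
# and the central-mismatch rule for the inhibition-mode call.

#' Default duplex scoring scheme
#'
#' Penalties per aligned miRNA position: match 0, G:U wobble 0.5, mismatch
#' 1.0, gap 2.0; penalties are doubled inside the core region (miRNA
#' positions 2-13 from the 5' end) when `core_double` is on. Scoring
#' covers the first `upsize` miRNA positions; 3' positions beyond that are
#' not scored.
#'
#' @param match,wobble,mismatch,gap Per-state penalties.
#' @param core Integer range of core positions (doubled penalties).
#' @param core_double Whether core doubling is applied.
#' @param upsize Number of 5' miRNA positions scored.
#' @param max_gaps Maximum gaps per duplex (0 or 1).
#' @return A list of scoring parameters.
#' @export
duplex_scheme <- function(match = 0, wobble = 0.5, mismatch = 1, gap = 2,
                          core = c(2L, 13L), core_double = TRUE,
                          upsize = 20L, max_gaps = 1L) {
  stopifnot(max_gaps %in% c(0L, 1L))
  list(
    match = match, wobble = wobble, mismatch = mismatch, gap = gap,
    core = as.integer(core), core_double = core_double,
    upsize = as.integer(upsize), max_gaps = as.integer(max_gaps)
  )
}

# state of one miRNA base against one target base (both 5'->3' characters,
# already antiparallel-opposed)
duplex_state <- function(m, t) {
  ifelse(
    (m == "A" & t == "U") | (m == "U" & t == "A") |
      (m == "C" & t == "G") | (m == "G" & t == "C"), "match",
    ifelse((m == "G" & t == "U") | (m == "U" & t == "G"), "wobble", "mismatch")
  )
}

state_penalty <- function(states, positions, scheme) {
  base <- c(
    match = scheme$match, wobble = scheme$wobble,
    mismatch = scheme$mismatch, gap = scheme$gap
  )[states]
  dbl <- scheme$core_double &
    positions >= scheme$core[1] & positions <= scheme$core[2]
  unname(base * ifelse(dbl, 2, 1))
}

#' Score a miRNA/target-site duplex
#'
#' Aligns the 5' `upsize` positions of the miRNA against the site
#' (antiparallel: miRNA position 1 opposes the last site base) and returns
#' the per-position states and the expectation (penalty sum). When the
#' site is one base shorter/longer than the scored miRNA region, the
#' single gap placement minimising the expectation is chosen by exhaustive
#' enumeration.
#'
#' @param mirna miRNA sequence, 5' to 3' (at least 15 nt).
#' @param site Target site subsequence, 5' to 3'; length must be within
#'   `max_gaps` of the scored miRNA length.
#' @param scheme Scoring parameters from [duplex_scheme()].
#' @return A `mir_duplex` list: `states` (per scored miRNA position),
#'   `expectation`, `mirna`, `site`.
#' @export
#' @examples
#' score_duplex("UGACAGAAGAGAGUGAGCACA", rev_comp("UGACAGAAGAGAGUGAGCACA"))
score_duplex <- function(mirna, site, scheme = duplex_scheme()) {
  mirna <- as_rna(mirna)
  site <- as_rna(site)
  if (nchar(mirna) < 15L) abort("miRNA must be at least 15 nt")
  U <- min(scheme$upsize, nchar(mirna))
  mvec <- strsplit(mirna, "", fixed = TRUE)[[1]][seq_len(U)]
  # the scored region opposes the *last* U-ish bases of the site; a site
  # longer than U + max_gaps is not a single binding site
  svec <- rev(strsplit(site, "", fixed = TRUE)[[1]])
  S <- length(svec)
  if (abs(S - U) > scheme$max_gaps) {
    abort(sprintf(
      "site length %d incompatible with scored miRNA length %d (max %d gap)",
      S, U, scheme$max_gaps
    ))
  }
  best <- NULL
  if (S == U) {
    states <- duplex_state(mvec, svec)
    best <- list(states = states, gap_at = NA_integer_)
  } else if (S == U - 1L) {
    # one miRNA base unopposed (deletion in target): try every placement
    for (g in seq_len(U)) {
      st <- character(U)
      st[g] <- "gap"
      idx <- setdiff(seq_len(U), g)
      st[idx] <- duplex_state(mvec[idx], svec)
      cand <- list(states = st, gap_at = g)
      if (is.null(best) || sum(state_penalty(cand$states, seq_len(U), scheme)) <
        sum(state_penalty(best$states, seq_len(U), scheme))) {
        best <- cand
      }
    }
  } else {
    # one extra target base bulged out; bulging out site element g leaves
    # U opposed bases, and the bulge is charged as a gap at the adjacent
    # miRNA position min(g, U)
    for (g in seq_len(U + 1L)) {
      svec_used <- svec[-g]
      st <- duplex_state(mvec, svec_used)
      pen <- sum(state_penalty(st, seq_len(U), scheme)) +
        state_penalty("gap", min(g, U), scheme)
      if (is.null(best) || pen < best$pen) {
        best <- list(states = st, gap_at = min(g, U), pen = pen)
      }
    }
  }
  positions <- seq_len(U)
  expectation <- if (!is.null(best$pen)) {
    best$pen
  } else {
    sum(state_penalty(best$states, positions, scheme))
  }
  structure(
    list(
      states = best$states, positions = positions,
      expectation = unname(expectation), gap_at = best$gap_at,
      mirna = mirna, site = site
    ),
    class = "mir_duplex"
  )
}

#' @export
print.mir_duplex <- function(x, ...) {
  glyph <- c(match = "|", wobble = "o", mismatch = "x", gap = "-")
  cat("<mir_duplex> expectation ", x$expectation, ", mode ",
    classify_mode(x), "\n",
    sep = ""
  )
  cat("5' ", paste(strsplit(x$mirna, "")[[1]][x$positions], collapse = ""),
    " 3' (miRNA)\n   ",
    paste(glyph[x$states], collapse = ""), "\n",
    sep = ""
  )
  invisible(x)
}

#' Classify the inhibition mode of a duplex
#'
#' Translational inhibition iff at least one *mismatch* (wobbles and gaps
#' do not count) falls at miRNA positions 9-11 (1-based from the 5' end);
#' otherwise cleavage.
#'
#' @param x A `mir_duplex` (or a character vector of states).
#' @param central Central positions triggering inhibition (default 9:11).
#' @return `"translational_inhibition"` or `"cleavage"`.
#' @export
classify_mode <- function(x, central = 9:11) {
  states <- if (inherits(x, "mir_duplex")) x$states else x
  if (any(states[central[central <= length(states)]] == "mismatch")) {
    "translational_inhibition"
  } else {
    "cleavage"
  }
}

#' Predict miRNA targets across a transcriptome
#'
#' Scans every transcript for candidate binding sites of each miRNA
#' (window lengths within one gap of the scored region), keeps locally
#' optimal non-overlapping sites per transcript, filters to
#' `expectation <= max_expectation`, sorts ascending by expectation
#' (ties: transcript id, then site start) and truncates to the `top_n`
#' best sites per miRNA.
#'
#' @param mirnas Tibble with `family` (or `id`) and `sequence`.
#' @param transcripts Tibble with `id`, `sequence`.
#' @param max_expectation Maximum expectation retained (default 3).
#' @param top_n Top target sites kept per miRNA (default 200).
#' @param scheme Scoring parameters from [duplex_scheme()].
#' @return Tibble: `mirna`, `transcript_id`, `site_start`, `site_end`,
#'   `expectation`, `mode`, `alignment` (match/wobble/mismatch/gap string
#'   over scored positions) and a `states` list-column.
#' @export
predict_targets <- function(mirnas, transcripts, max_expectation = 3,
                            top_n = 200L, scheme = duplex_scheme()) {
  stopifnot(max_expectation >= 0, top_n >= 1L)
  name_col <- if ("family" %in% names(mirnas)) "family" else "id"
  out <- list()
  for (mi in seq_len(nrow(mirnas))) {
    mseq <- as_rna(mirnas$sequence[mi])
    hits <- list()
    for (ti in seq_len(nrow(transcripts))) {
      tseq <- as_rna(transcripts$sequence[ti])
      sc <- scan_sites(mseq, tseq, scheme)
      if (nrow(sc) == 0L) next
      sc$mirna <- mirnas[[name_col]][mi]
      sc$transcript_id <- transcripts$id[ti]
      hits[[length(hits) + 1L]] <- sc
    }
    if (length(hits) == 0L) next
    hits <- dplyr::bind_rows(hits)
    # keep locally optimal non-overlapping sites per transcript
    hits <- dplyr::bind_rows(lapply(
      split(hits, hits$transcript_id),
      prune_overlapping_sites
    ))
    hits <- dplyr::filter(hits, .data$expectation <= max_expectation)
    if (nrow(hits) == 0L) next
    # re-score the retained sites for states / mode / alignment
    details <- purrr::pmap(
      list(hits$transcript_id, hits$site_start, hits$site_end),
      function(tid, s, e) {
        tseq <- as_rna(transcripts$sequence[transcripts$id == tid][1])
        score_duplex(mseq, substr(tseq, s, e), scheme)
      }
    )
    hits$mode <- vapply(details, classify_mode, character(1))
    hits$alignment <- vapply(details, function(d) {
      paste(
        c(match = "|", wobble = "o", mismatch = "x", gap = "-")[d$states],
        collapse = ""
      )
    }, character(1))
    hits$states <- purrr::map(details, "states")
    hits <- dplyr::arrange(
      hits, .data$expectation, .data$transcript_id, .data$site_start
    )
    hits <- dplyr::select(
      hits, "mirna", "transcript_id", "site_start", "site_end",
      "expectation", "mode", "alignment", "states"
    )
    out[[length(out) + 1L]] <- head(hits, top_n)
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      mirna = character(), transcript_id = character(),
      site_start = integer(), site_end = integer(),
      expectation = double(), mode = character(), alignment = character(),
      states = list()
    ))
  }
  dplyr::bind_rows(out)
}

# Vectorized site scan: minimal expectation for every candidate window of
# the transcript (ungapped, one target deletion, one target insertion).
# Equivalent to calling score_duplex() on every window; kept in lockstep by
# a property test.
scan_sites <- function(mirna, tseq, scheme) {
  mirna <- as_rna(mirna)
  if (nchar(mirna) < 15L) abort("miRNA must be at least 15 nt")
  U <- min(scheme$upsize, nchar(mirna))
  m <- encode_rna(substr(mirna, 1L, U)) + 1L
  t <- encode_rna(tseq) + 1L
  n <- length(t)
  # penalty lookup: rows = miRNA base, cols = target base (A C G U N)
  pen <- matrix(scheme$mismatch, 5, 5)
  pen[1, 4] <- pen[4, 1] <- pen[2, 3] <- pen[3, 2] <- scheme$match
  pen[3, 4] <- pen[4, 3] <- scheme$wobble
  dbl <- ifelse(
    scheme$core_double & seq_len(U) >= scheme$core[1] &
      seq_len(U) <= scheme$core[2], 2, 1
  )
  gap_at <- scheme$gap * dbl

  res <- list()
  # ungapped window, length U: miRNA k opposes tvec[s + U - k]
  if (n >= U) {
    ns <- n - U + 1L
    tot <- numeric(ns)
    for (k in seq_len(U)) {
      tot <- tot + pen[m[k], ][t[seq_len(ns) + U - k]] * dbl[k]
    }
    res[[length(res) + 1L]] <- tibble::tibble(
      site_start = seq_len(ns), site_end = seq_len(ns) + U - 1L,
      expectation = tot
    )
  }
  if (scheme$max_gaps >= 1L) {
    # target deletion, window length U - 1: gap at miRNA position g;
    # k < g opposes element k, k > g opposes element k - 1
    L <- U - 1L
    if (L >= 1L && n >= L) {
      ns <- n - L + 1L
      A <- matrix(0, U, ns)
      B <- matrix(0, U, ns)
      for (k in seq_len(U)) {
        if (k <= L) A[k, ] <- pen[m[k], ][t[seq_len(ns) + L - k]] * dbl[k]
        if (k >= 2L) B[k, ] <- pen[m[k], ][t[seq_len(ns) + L - k + 1L]] * dbl[k]
      }
      prefA <- apply(A, 2, cumsum)
      cumB <- apply(B, 2, cumsum)
      totB <- cumB[U, ]
      best <- rep(Inf, ns)
      for (g in seq_len(U)) {
        before <- if (g > 1L) prefA[g - 1L, ] else 0
        after <- totB - cumB[g, ]
        best <- pmin(best, before + gap_at[g] + after)
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        site_start = seq_len(ns), site_end = seq_len(ns) + L - 1L,
        expectation = best
      )
    }
    # target insertion, window length U + 1: site element g bulged out;
    # k < g opposes element k, k >= g opposes element k + 1
    L <- U + 1L
    if (n >= L) {
      ns <- n - L + 1L
      C <- matrix(0, U, ns)
      D <- matrix(0, U, ns)
      for (k in seq_len(U)) {
        C[k, ] <- pen[m[k], ][t[seq_len(ns) + L - k]] * dbl[k]
        D[k, ] <- pen[m[k], ][t[seq_len(ns) + L - k - 1L]] * dbl[k]
      }
      prefC <- apply(C, 2, cumsum)
      cumD <- apply(D, 2, cumsum)
      totD <- cumD[U, ]
      best <- rep(Inf, ns)
      for (g in seq_len(U + 1L)) {
        before <- if (g > 1L) prefC[min(g - 1L, U), ] else 0
        after <- if (g <= U) totD - (if (g > 1L) cumD[g - 1L, ] else 0) else 0
        best <- pmin(best, before + gap_at[min(g, U)] + after)
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        site_start = seq_len(ns), site_end = seq_len(ns) + L - 1L,
        expectation = best
      )
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(
      site_start = integer(), site_end = integer(), expectation = double()
    ))
  }
  dplyr::bind_rows(res)
}

# greedy selection of non-overlapping sites by ascending expectation
# (ties: start position) within one transcript
prune_overlapping_sites <- function(hits) {
  hits <- dplyr::arrange(hits, .data$expectation, .data$site_start)
  kept <- logical(0)
  starts <- integer(0)
  ends <- integer(0)
  keep_rows <- integer(0)
  for (r in seq_len(nrow(hits))) {
    s <- hits$site_start[r]
    e <- hits$site_end[r]
    if (!any(s <= ends & e >= starts)) {
      keep_rows <- c(keep_rows, r)
      starts <- c(starts, s)
      ends <- c(ends, e)
    }
  }
  hits[sort(keep_rows), ]
}

#' Flanked region around a target site
#'
#' Returns the site extended by `up` bases upstream and `down` bases
#' downstream, clipped at the transcript bounds (used by the optional
#' target-accessibility hook; defaults 17/13).
#'
#' @param transcript Transcript sequence (single string).
#' @param start,end 1-based inclusive site coordinates.
#' @param up,down Flank lengths (defaults 17 and 13).
#' @return List with `sequence`, `start`, `end` of the flanked region.
#' @export
site_flanks <- function(transcript, start, end, up = 17L, down = 13L) {
  stopifnot(up >= 0L, down >= 0L, start >= 1L, end >= start)
  transcript <- as_rna(transcript)
  tlen <- nchar(transcript)
  stopifnot(end <= tlen)
  s <- max(1L, start - up)
  e <- min(tlen, end + down)
  list(sequence = substr(transcript, s, e), start = s, end = e)
}

#' Target-site accessibility (optional hook)
#'
#' Energy needed to unpair a target site: the MFE of the flanked region
#' is compared with the MFE when the site bases are masked (forced
#' unpaired). Uses the built-in folding model, whose absolute energy scale
#' differs from RNAup-style calculations; off by default in the pipeline.
#'
#' @param transcript Transcript sequence.
#' @param start,end Site coordinates.
#' @param up,down Flank lengths (defaults 17/13).
#' @param params Folding model parameters.
#' @return Unpairing energy (kcal/mol, non-negative).
#' @export
site_unpair_energy <- function(transcript, start, end, up = 17L, down = 13L,
                               params = fold_energy_params()) {
  region <- site_flanks(transcript, start, end, up = up, down = down)
  free <- fold_rna(region$sequence, params = params)$mfe
  masked <- region$sequence
  substr(masked, start - region$start + 1L, end - region$start + 1L) <-
    strrep("N", end - start + 1L)
  forced <- fold_rna(masked, params = params)$mfe
  max(0, forced - free)
}
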