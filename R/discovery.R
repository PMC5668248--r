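# Homology-based miRNA precursor discovery: scan transcripts for windows
# matching mature reference sequences, cut a precursor window around each
# match, fold it, and apply the six hairpin acceptance criteria.

#' Find mature-miRNA homology matches in transcripts
#'
#' Every window of each transcript (forward strand and reverse complement)
#' is compared against every mature reference sequence; windows with at
#' most `max_mismatches` substitutions are kept. Each match gets an
#' expectation-style e-value `database_length * transcript_length *
#' 4^-(matched positions)` (database length = total mature reference
#' length); matches above `evalue_cutoff` are dropped. Matches with zero
#' mismatches carry the reference family name; mismatched matches are
#' labelled putative (`miR-f` prefix on the transcript id) since family
#' assignment requires 100% identity.
#'
#' @param transcripts Tibble with `id`, `sequence` (from [read_fasta()]).
#' @param mature Tibble with `id`, `sequence`; mature sequences must be
#'   15-30 nt.
#' @param max_mismatches Maximum substitutions retained (default 4).
#' @param evalue_cutoff E-value filter (default 1e-5).
#' @return Tibble of matches: `transcript_id`, `mature_id`, `family`,
#'   `start`, `end` (1-based inclusive, forward coordinates), `strand`
#'   (`+`/`-`), `mismatches`, `evalue`, `mature_length`, sorted by
#'   (transcript_id, start).
#' @export
find_mature_matches <- function(transcripts, mature, max_mismatches = 4L,
                                evalue_cutoff = 1e-5) {
  stopifnot(all(c("id", "sequence") %in% names(transcripts)))
  stopifnot(all(c("id", "sequence") %in% names(mature)))
  mature$sequence <- as_rna(mature$sequence)
  if (any(nchar(mature$sequence) < 15L)) {
    abort("mature miRNA sequences must be at least 15 nt")
  }
  db_length <- sum(nchar(mature$sequence))
  rows <- list()
  for (ti in seq_len(nrow(transcripts))) {
    tseq <- as_rna(transcripts$sequence[ti])
    tlen <- nchar(tseq)
    tvec_fwd <- strsplit(tseq, "", fixed = TRUE)[[1]]
    tvec_rev <- strsplit(rev_comp(tseq), "", fixed = TRUE)[[1]]
    for (mi in seq_len(nrow(mature))) {
      mvec <- strsplit(mature$sequence[mi], "", fixed = TRUE)[[1]]
      L <- length(mvec)
      if (L > tlen) next
      for (strand in c("+", "-")) {
        tvec <- if (strand == "+") tvec_fwd else tvec_rev
        mm <- sliding_mismatches(tvec, mvec)
        hits <- which(mm <= max_mismatches)
        for (s in hits) {
          n_mm <- mm[s]
          ev <- db_length * tlen * 4^-(L - n_mm)
          if (ev > evalue_cutoff) next
          # report forward-strand coordinates
          start <- if (strand == "+") s else tlen - (s + L - 1L) + 1L
          fam <- mirna_family(mature$id[mi])
          # family assignment needs 100% identity; mismatched retained
          # candidates get a putative miR-f-style label
          if (n_mm > 0L) fam <- sub("^miR-", "miR-f", fam)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            transcript_id = transcripts$id[ti],
            mature_id = mature$id[mi],
            family = fam,
            start = start, end = start + L - 1L,
            strand = strand, mismatches = n_mm, evalue = ev,
            mature_length = L
          )
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(
      transcript_id = character(), mature_id = character(),
      family = character(), start = integer(), end = integer(),
      strand = character(), mismatches = integer(), evalue = double(),
      mature_length = integer()
    )
  }
  dplyr::arrange(out, .data$transcript_id, .data$start, .data$mature_id)
}

# mismatch count of the query at every start position of the subject
sliding_mismatches <- function(subject, query) {
  n <- length(subject)
  L <- length(query)
  n_win <- n - L + 1L
  if (n_win < 1L) return(integer(0))
  mm <- integer(n_win)
  for (k in seq_len(L)) {
    mm <- mm + (subject[k:(k + n_win - 1L)] != query[k])
  }
  mm
}

#' Extract precursor windows around mature matches
#'
#' Cuts `[max(1, start - flank), min(len, end + flank)]` out of each
#' matched transcript and recomputes the mature span in window
#' coordinates. Minus-strand matches are extracted as the reverse
#' complement of the window so the mature sequence reads 5' to 3'.
#'
#' @param transcripts Tibble with `id`, `sequence`.
#' @param matches Output of [find_mature_matches()].
#' @param flank Bases kept on each side of the mature match (default 120).
#' @return Tibble of precursor candidates (pre-fold): match columns plus
#'   `window_start`, `window_end` (transcript coordinates),
#'   `window_sequence`, `mature_start`, `mature_end` (window coordinates).
#' @export
extract_precursors <- function(transcripts, matches, flank = 120L) {
  stopifnot(flank >= 0L)
  seqs <- setNames(as_rna(transcripts$sequence), transcripts$id)
  purrr::pmap_dfr(matches, function(transcript_id, start, end, strand,
                                    mature_length, ...) {
    tseq <- seqs[[transcript_id]]
    tlen <- nchar(tseq)
    ws <- max(1L, start - flank)
    we <- min(tlen, end + flank)
    window <- substr(tseq, ws, we)
    if (strand == "+") {
      ms <- start - ws + 1L
    } else {
      window <- rev_comp(window)
      ms <- we - end + 1L
    }
    tibble::tibble(
      transcript_id = transcript_id, start = start, end = end,
      strand = strand, mature_length = mature_length, ...,
      window_start = ws, window_end = we, window_sequence = window,
      mature_start = ms, mature_end = ms + mature_length - 1L
    )
  })
}

#' Apply the six precursor acceptance criteria
#'
#' Folds each precursor window with [fold_rna()] and evaluates:
#' \describe{
#'   \item{is_candidate}{the window holds a homology match (true by
#'     construction for windows from [extract_precursors()]).}
#'   \item{has_hairpin}{the structure has a stem of at least
#'     `min_stem_pairs` pairs enclosing a single terminal loop.}
#'   \item{mature_in_one_arm}{every mature position classifies to the same
#'     hairpin arm via [arm_of()].}
#'   \item{duplex_mismatch_ok}{[duplex_mismatches()] is strictly below
#'     `max_duplex_mismatches`; vacuously true when the mature does not
#'     lie in one arm (the duplex is then undefined and criterion 3
#'     already fails).}
#'   \item{no_loop_or_break}{no mature position falls in the terminal loop
#'     and no unpaired run of 3+ bases splits the mature pairing block.}
#'   \item{mfe_ok}{window MFE at most `mfe_threshold` kcal/mol.}
#' }
#' `accepted` is the conjunction of all six.
#'
#' @param precursors Output of [extract_precursors()].
#' @param mfe_threshold MFE acceptance bound, kcal/mol (default -20).
#' @param max_duplex_mismatches Strict upper bound on arm-duplex
#'   mismatches (default 7, i.e. fewer than seven).
#' @param min_stem_pairs Minimum stem size for a hairpin (default 12).
#' @param params Folding model parameters.
#' @return `precursors` with a `fold` list-column, `mfe`, the six logical
#'   criteria columns and `accepted`.
#' @export
# the six criterion verdicts for one folded window with the mature at
# [ms, me]; shared by evaluate_criteria() and the synthetic generator's
# plant verification
criterion_flags <- function(fold, ms, me, mfe_threshold = -20,
                            max_duplex_mismatches = 7L,
                            min_stem_pairs = 12L) {
  span <- ms:me
  arms <- arm_of(fold, span)
  stem <- maximal_stem(fold)
  has_hairpin <- !is.null(stem) && stem$n_pairs >= min_stem_pairs
  in_one_arm <- all(arms == "five_prime_arm") ||
    all(arms == "three_prime_arm")
  duplex_ok <- TRUE
  n_duplex_mm <- NA_integer_
  if (in_one_arm) {
    n_duplex_mm <- duplex_mismatches(fold, ms, me)
    duplex_ok <- n_duplex_mm < max_duplex_mismatches
  }
  paired <- fold$pair_table[span] > 0L
  no_break <- TRUE
  if (any(paired)) {
    block <- seq(which(paired)[1], rev(which(paired))[1])
    runs <- rle(paired[block])
    no_break <- !any(runs$lengths >= 3L & !runs$values)
  }
  no_loop_or_break <- !any(arms == "loop") && no_break
  tibble::tibble(
    mfe = fold$mfe,
    duplex_mismatch_count = n_duplex_mm,
    is_candidate = TRUE,
    has_hairpin = has_hairpin,
    mature_in_one_arm = in_one_arm,
    duplex_mismatch_ok = duplex_ok,
    no_loop_or_break = no_loop_or_break,
    mfe_ok = fold$mfe <= mfe_threshold
  )
}

evaluate_criteria <- function(precursors, mfe_threshold = -20,
                              max_duplex_mismatches = 7L,
                              min_stem_pairs = 12L,
                              params = fold_energy_params()) {
  folds <- purrr::map(precursors$window_sequence, fold_rna, params = params)
  crit <- purrr::pmap_dfr(
    list(folds, precursors$mature_start, precursors$mature_end),
    criterion_flags,
    mfe_threshold = mfe_threshold,
    max_duplex_mismatches = max_duplex_mismatches,
    min_stem_pairs = min_stem_pairs
  )
  out <- dplyr::bind_cols(precursors, crit)
  out$fold <- folds
  out$accepted <- out$is_candidate & out$has_hairpin &
    out$mature_in_one_arm & out$duplex_mismatch_ok &
    out$no_loop_or_break & out$mfe_ok
  out
}

#' Collapse accepted candidates into a family inventory
#'
#' One entry per distinct miRNA family (redundant isoform entries
#' removed); candidates with homology mismatches keep their putative
#' family label.
#'
#' @param candidates Tibble with `family` (and optionally `accepted`,
#'   which is filtered on when present).
#' @param condition Condition label recorded on every row.
#' @return A `mir_inventory` tibble: `family`, `condition`,
#'   `n_candidates`, sorted by family.
#' @export
build_inventory <- function(candidates, condition) {
  if ("accepted" %in% names(candidates)) {
    candidates <- dplyr::filter(candidates, .data$accepted)
  }
  out <- dplyr::count(
    dplyr::mutate(candidates, family = mirna_family(.data$family)),
    .data$family,
    name = "n_candidates"
  )
  out$condition <- condition
  out <- dplyr::arrange(
    dplyr::select(out, "family", "condition", "n_candidates"),
    .data$family
  )
  class(out) <- c("mir_inventory", class(out))
  out
}

#' One-call miRNA identification
#'
#' Convenience wrapper chaining [find_mature_matches()],
#' [extract_precursors()], [evaluate_criteria()] and [build_inventory()].
#'
#' @inheritParams find_mature_matches
#' @inheritParams extract_precursors
#' @inheritParams evaluate_criteria
#' @param condition Condition label for the inventory.
#' @return List with `candidates` (all evaluated precursors) and
#'   `inventory` (accepted families).
#' @export
identify_mirnas <- function(transcripts, mature, condition = "sample",
                            max_mismatches = 4L, evalue_cutoff = 1e-5,
                            flank = 120L, mfe_threshold = -20,
                            max_duplex_mismatches = 7L,
                            min_stem_pairs = 12L,
                            params = fold_energy_params()) {
  matches <- find_mature_matches(
    transcripts, mature,
    max_mismatches = max_mismatches, evalue_cutoff = evalue_cutoff
  )
  if (nrow(matches) == 0L) {
    return(list(
      candidates = matches,
      inventory = build_inventory(
        tibble::tibble(family = character()), condition
      )
    ))
  }
  pre <- extract_precursors(transcripts, matches, flank = flank)
  cand <- evaluate_criteria(
    pre,
    mfe_threshold = mfe_threshold,
    max_duplex_mismatches = max_duplex_mismatches,
    min_stem_pairs = min_stem_pairs, params = params
  )
  list(
    candidates = cand,
    inventory = build_inventory(cand, condition)
  )
}
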