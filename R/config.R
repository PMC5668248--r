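# Pipeline configuration: every tunable of the six stages with its
# default. Defaults follow the published parameter set where one is
# stated (expectation <= 3, top 200 targets, 17/13 accessibility flanks,
# central mismatch 9-11, MFE <= -20 kcal/mol, e-value 1e-5, weights
# 0.4/0.3/0.3, k = 20).

#' Pipeline run configuration
#'
#' @param seed Integer seed driving all randomness.
#' @param mfe_threshold Precursor MFE acceptance bound, kcal/mol.
#' @param evalue_cutoff Homology e-value cutoff.
#' @param max_mismatches Maximum homology mismatches retained for folding.
#' @param max_duplex_mismatches Strict bound on arm-duplex mismatches.
#' @param min_stem_pairs Minimum hairpin stem size.
#' @param flank Precursor window flank, nt each side.
#' @param max_expectation Maximum target expectation score.
#' @param top_n Top target sites per miRNA.
#' @param core_double Double penalties in the miRNA core region (2-13).
#' @param central_mismatch Positions whose mismatch calls translational
#'   inhibition.
#' @param flank_up,flank_down Accessibility flanks around a target site.
#' @param accessibility Whether the unpairing-energy filter runs.
#' @param max_unpair_energy Maximum energy to unpair the target site
#'   (only used when `accessibility` is on; otherwise ignored with a
#'   warning at run time).
#' @param alpha GO node-score decay per edge.
#' @param go_namespace GO namespace scored.
#' @param min_score GO cluster filter threshold.
#' @param weights Co-expression component weights (abundance, go, pcc).
#' @param k Co-expression neighbours per query.
#' @return A `mir_run_config` list.
#' @export
#' @examples
#' run_config()$max_expectation
run_config <- function(seed = 1L,
                       mfe_threshold = -20,
                       evalue_cutoff = 1e-5,
                       max_mismatches = 4L,
                       max_duplex_mismatches = 7L,
                       min_stem_pairs = 12L,
                       flank = 120L,
                       max_expectation = 3,
                       top_n = 200L,
                       core_double = TRUE,
                       central_mismatch = 9:11,
                       flank_up = 17L,
                       flank_down = 13L,
                       accessibility = FALSE,
                       max_unpair_energy = 25,
                       alpha = 0.6,
                       go_namespace = "BP",
                       min_score = 0,
                       weights = c(abundance = 0.4, go = 0.3, pcc = 0.3),
                       k = 20L) {
  if (abs(sum(weights) - 1) > 1e-9) abort("weights must sum to 1")
  structure(
    list(
      seed = as.integer(seed), mfe_threshold = mfe_threshold,
      evalue_cutoff = evalue_cutoff,
      max_mismatches = as.integer(max_mismatches),
      max_duplex_mismatches = as.integer(max_duplex_mismatches),
      min_stem_pairs = as.integer(min_stem_pairs),
      flank = as.integer(flank),
      max_expectation = max_expectation, top_n = as.integer(top_n),
      core_double = core_double,
      central_mismatch = as.integer(central_mismatch),
      flank_up = as.integer(flank_up), flank_down = as.integer(flank_down),
      accessibility = accessibility,
      max_unpair_energy = max_unpair_energy,
      alpha = alpha, go_namespace = go_namespace, min_score = min_score,
      weights = weights, k = as.integer(k)
    ),
    class = "mir_run_config"
  )
}

#' @export
print.mir_run_config <- function(x, ...) {
  cat("<mir_run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}
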