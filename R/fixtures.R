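# Packaged transcriptions of the published miRNA-target tables for the
# healthy (JH) / virus-infected (JV) Jatropha comparison, used as desk-scale
# fixtures throughout the pipeline. The symbol-to-target synonym table is
# our own transcription (the source tables use long names in the target
# tables and gene symbols in the co-expression table).

#' Load the packaged miRNA-target fixture tables
#'
#' Returns transcriptions of the published comparison tables:
#' `common_targets` (targets of miRNA families found in both conditions,
#' with per-condition FPKM and the printed regulation call),
#' `unique_targets` (targets of condition-specific miRNA families),
#' `coexpr_genes` (query genes with their reported top co-expressed genes
#' and pathways) and `synonyms` (gene symbol to long target name). The
#' loader is pure: repeated calls return identical objects.
#'
#' @return A `mir_fixture_tables` list of tibbles.
#' @export
#' @examples
#' fx <- load_fixture_tables()
#' nrow(fx$common_targets)
load_fixture_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "mirframe", mustWork = TRUE)
  common <- readr::read_tsv(
    path("table1_common_mirna_targets.tsv"),
    col_types = readr::cols(
      row_id = "c", mirna = "c", jh_target = "c", jv_target = "c",
      jh_fpkm = "d", jv_fpkm = "d", regulation = "c"
    )
  )
  unique_t <- readr::read_tsv(
    path("table2_unique_mirna_targets.tsv"),
    col_types = readr::cols(
      row_id = "c", mirna = "c", target = "c", condition = "c", fpkm = "d"
    )
  )
  coexpr <- readr::read_tsv(
    path("table3_coexpression.tsv"),
    col_types = readr::cols(.default = "c")
  )
  syn <- readr::read_tsv(
    path("gene_synonyms.tsv"),
    col_types = readr::cols(.default = "c")
  )
  stopifnot(
    all(common$regulation %in% c("up", "down", "absent")),
    all(unique_t$condition %in% c("JH", "JV"))
  )
  structure(
    list(
      common_targets = common, unique_targets = unique_t,
      coexpr_genes = coexpr, synonyms = syn
    ),
    class = "mir_fixture_tables"
  )
}

#' @export
print.mir_fixture_tables <- function(x, ...) {
  cat("<mir_fixture_tables>\n")
  cat("  common_targets:", nrow(x$common_targets), "rows\n")
  cat("  unique_targets:", nrow(x$unique_targets), "rows\n")
  cat("  coexpr_genes:  ", nrow(x$coexpr_genes), "rows\n")
  invisible(x)
}

# normalized matching key for target names that differ only in punctuation
# between the two condition columns
normalize_target_name <- function(x) {
  x <- stringr::str_remove_all(x, "\\s*\\[EC:[^]]*\\]")
  x <- tolower(x)
  x <- stringr::str_replace_all(x, "[^a-z0-9]+", " ")
  stringr::str_trim(x)
}

#' Per-condition miRNA-target tables from the fixtures
#'
#' Flattens the fixture tables into a single long table for one condition:
#' one row per (miRNA family, target) with its FPKM.
#'
#' @param fixtures A `mir_fixture_tables` (default: freshly loaded).
#' @param condition `"JH"` or `"JV"`.
#' @return Tibble with `mirna`, `target`, `target_key`, `fpkm`,
#'   `condition`.
#' @export
fixture_condition_targets <- function(fixtures = load_fixture_tables(),
                                      condition = c("JH", "JV")) {
  condition <- match.arg(condition)
  ct <- fixtures$common_targets
  if (condition == "JH") {
    common <- dplyr::transmute(
      dplyr::filter(ct, !is.na(.data$jh_target)),
      mirna = .data$mirna, target = .data$jh_target, fpkm = .data$jh_fpkm
    )
  } else {
    common <- dplyr::transmute(
      dplyr::filter(ct, !is.na(.data$jv_target)),
      mirna = .data$mirna, target = .data$jv_target, fpkm = .data$jv_fpkm
    )
  }
  uniq <- dplyr::transmute(
    dplyr::filter(fixtures$unique_targets, .data$condition == !!condition),
    mirna = .data$mirna, target = .data$target, fpkm = .data$fpkm
  )
  out <- dplyr::bind_rows(common, uniq)
  out$target_key <- normalize_target_name(out$target)
  out$condition <- condition
  dplyr::arrange(out, .data$mirna, .data$target_key)
}

#' Check printed regulation calls against the numeric FPKM rule
#'
#' Recomputes regulation (`up` iff JV FPKM > JH FPKM, `down` iff smaller,
#' `unchanged` iff equal) for every fixture row carrying both FPKM values
#' and reports rows whose printed arrow disagrees. The published table
#' contains one such row.
#'
#' @param fixtures A `mir_fixture_tables`.
#' @return Tibble of discrepant rows (`row_id`, `mirna`, printed and
#'   computed regulation); a message lists them.
#' @export
validate_fixture_regulation <- function(fixtures = load_fixture_tables()) {
  ct <- dplyr::filter(
    fixtures$common_targets,
    !is.na(.data$jh_fpkm) & !is.na(.data$jv_fpkm)
  )
  ct$computed <- regulation_call(ct$jh_fpkm, ct$jv_fpkm)
  bad <- dplyr::filter(ct, .data$computed != .data$regulation)
  bad <- dplyr::select(
    bad, "row_id", "mirna", "jh_fpkm", "jv_fpkm",
    printed = "regulation", computed = "computed"
  )
  if (nrow(bad) > 0L) {
    inform(paste0(
      "fixture regulation arrows disagreeing with the FPKM rule: row ",
      paste(bad$row_id, collapse = ", ")
    ))
  }
  bad
}

regulation_call <- function(fpkm_a, fpkm_b) {
  dplyr::case_when(
    fpkm_b > fpkm_a ~ "up",
    fpkm_b < fpkm_a ~ "down",
    TRUE ~ "unchanged"
  )
}
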