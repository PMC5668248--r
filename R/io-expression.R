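# Expression tables (long FPKM format) and GO annotation tables.

#' Validate (and coerce) an expression table
#'
#' An expression table is a long-format data frame with columns
#' `transcript_id`, `condition`, `replicate` and `fpkm`. The
#' (transcript, condition, replicate) triple must be unique, FPKM values
#' non-negative, and at least one condition present.
#'
#' @param x A data frame.
#' @return The validated table as a tibble.
#' @export
as_expression_table <- function(x) {
  needed <- c("transcript_id", "condition", "replicate", "fpkm")
  if (!all(needed %in% names(x))) {
    abort(paste0(
      "expression table needs columns: ",
      paste(setdiff(needed, names(x)), collapse = ", ")
    ))
  }
  x <- tibble::as_tibble(x)
  x$replicate <- as.integer(x$replicate)
  if (any(x$replicate < 1L)) abort("replicate indices must be >= 1")
  if (any(x$fpkm < 0)) abort("fpkm values must be non-negative")
  if (nrow(x) > 0L && length(unique(x$condition)) < 1L) {
    abort("at least one condition is required")
  }
  key <- paste(x$transcript_id, x$condition, x$replicate)
  if (anyDuplicated(key)) {
    abort("duplicate (transcript_id, condition, replicate) rows")
  }
  x
}

#' Read an expression table from TSV
#'
#' @param path TSV with columns `transcript_id`, `condition`, `replicate`,
#'   `fpkm`.
#' @return A validated expression tibble.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  as_expression_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' Read transcript-to-GO annotations from TSV
#'
#' Duplicate (transcript, term) pairs are collapsed; every term must exist
#' in the supplied DAG.
#'
#' @param path TSV with columns `transcript_id`, `go_term`.
#' @param dag A `mir_go_dag` the terms must belong to.
#' @return A tibble with columns `transcript_id`, `go_term`.
#' @export
read_go_annotations <- function(path, dag) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  as_go_annotations(ann, dag)
}

#' @rdname read_go_annotations
#' @param x A data frame with columns `transcript_id`, `go_term`.
#' @export
as_go_annotations <- function(x, dag) {
  needed <- c("transcript_id", "go_term")
  if (!all(needed %in% names(x))) {
    abort("annotations need columns transcript_id, go_term")
  }
  x <- dplyr::distinct(tibble::as_tibble(x[needed]))
  if (inherits(dag, "mir_go_dag")) {
    unknown <- setdiff(x$go_term, dag$terms$id)
    if (length(unknown) > 0L) {
      abort(paste0(
        "annotation term(s) not in DAG: ",
        paste(head(unknown, 5L), collapse = ", ")
      ))
    }
  }
  x
}
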