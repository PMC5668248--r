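# FASTA input/output. Sequences are normalized to RNA space (U) on load;
# the id is the first whitespace token of the header, the remainder is kept
# as the description.

#' Read a FASTA file of transcripts or mature miRNAs
#'
#' @param path Path to a FASTA file.
#' @param kind `"transcript"` or `"mature_mirna"`; recorded per row.
#' @return A tibble with columns `id`, `description`, `sequence` (RNA,
#'   uppercase, U-normalized), `kind` and `length`.
#' @export
read_fasta <- function(path, kind = c("transcript", "mature_mirna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  validate_fasta_lines(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    return(tibble::tibble(
      id = character(), description = character(),
      sequence = character(), kind = character(), length = integer()
    ))
  }
  headers <- names(set)
  id <- stringr::str_extract(headers, "^\\S+")
  desc <- stringr::str_trim(stringr::str_remove(headers, "^\\S+"))
  if (anyDuplicated(id)) {
    abort(paste0(
      "duplicate sequence ids in ", path, ": ",
      paste(unique(id[duplicated(id)]), collapse = ", ")
    ))
  }
  seqs <- as_rna(as.character(set))
  tibble::tibble(
    id = id, description = desc, sequence = unname(seqs),
    kind = kind, length = nchar(seqs)
  )
}

# cheap structural scan so parse errors can name the offending line
validate_fasta_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(invisible(TRUE))
  nonempty <- which(stringr::str_trim(lines) != "")
  if (length(nonempty) == 0L) return(invisible(TRUE))
  if (!startsWith(lines[nonempty[1]], ">")) {
    abort(sprintf("FASTA parse error at line %d: expected '>' header", nonempty[1]))
  }
  headers <- which(startsWith(lines, ">"))
  for (h in headers) {
    if (stringr::str_trim(substring(lines[h], 2)) == "") {
      abort(sprintf("FASTA parse error at line %d: empty header", h))
    }
    nxt <- lines[seq(h + 1, length.out = max(0, length(lines) - h))]
    body <- character(0)
    for (ln in nxt) {
      if (startsWith(ln, ">")) break
      body <- c(body, stringr::str_trim(ln))
    }
    if (sum(nchar(body)) == 0L) {
      abort(sprintf("FASTA parse error at line %d: record has empty sequence", h))
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA
#'
#' Headers are `id` followed by `description` when present. Output order
#' follows the row order of `seqs`.
#'
#' @param seqs A tibble with at least `id` and `sequence` columns
#'   (as returned by [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "sequence") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) {
    seqs$description
  } else {
    rep("", nrow(seqs))
  }
  headers <- ifelse(is.na(desc) | desc == "", seqs$id, paste(seqs$id, desc))
  set <- Biostrings::BStringSet(setNames(as_rna(seqs$sequence), headers))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
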