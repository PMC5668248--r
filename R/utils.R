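# Internal sequence helpers. All sequences are held as RNA (U, never T),
# uppercase, alphabet {A, C, G, U, N}.

RNA_LETTERS <- c("A", "C", "G", "U", "N")

#' Normalize a nucleotide string to RNA space
#'
#' Uppercases and converts T to U. Errors on letters outside
#' \{A, C, G, U, T, N\}.
#'
#' @param x Character vector of sequences.
#' @return Character vector of RNA sequences.
#' @export
#' @examples
#' as_rna("acgt")
as_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    abort(sprintf(
      "invalid nucleotide letters in sequence(s): %s",
      paste(head(which(bad), 3L), collapse = ", ")
    ))
  }
  x
}

# integer encoding used by the folding engine: A=0, C=1, G=2, U=3, N=4
encode_rna <- function(sequence) {
  v <- strsplit(sequence, "", fixed = TRUE)[[1]]
  codes <- match(v, RNA_LETTERS) - 1L
  if (anyNA(codes)) abort("sequence contains letters outside {A,C,G,U,N}")
  codes
}

decode_rna <- function(codes) paste(RNA_LETTERS[codes + 1L], collapse = "")

#' Reverse complement in RNA space
#'
#' @param x Character vector of RNA sequences (A/C/G/U/N).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' rev_comp("GGAAC")
rev_comp <- function(x) {
  x <- as_rna(x)
  comp <- chartr("ACGUN", "UGCAN", x)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(v) paste(rev(v), collapse = ""),
    character(1)
  )
}

# TRUE where the two bases form a Watson-Crick or G:U pair
bases_pair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "U") | (a == "U" & b == "G")
}

# canonical miRNA family name: keep the miR-number token, drop species
# prefixes and letter suffixes (ath-miR156a -> miR-156; miR-f11908 stays).
#' Canonical miRNA family name
#'
#' Collapses variant mature names onto their family: species prefixes and
#' trailing lettered isoform suffixes are dropped and the `miR-<number>`
#' (or `miR-f<number>` for novel families) token is kept.
#'
#' @param x Character vector of mature miRNA names.
#' @return Character vector of family names.
#' @export
#' @examples
#' mirna_family(c("ath-miR156a", "miR-5658", "miR-f11908"))
mirna_family <- function(x) {
  m <- stringr::str_match(x, stringr::regex("mir-?(f?)0*(\\d+)", ignore_case = TRUE))
  out <- ifelse(is.na(m[, 3]), x, paste0("miR-", m[, 2], m[, 3]))
  out
}

random_rna <- function(n, length, letters = c("A", "C", "G", "U"),
                       prob = NULL) {
  len <- rep_len(length, n)
  vapply(seq_len(n), function(i) {
    paste(sample(letters, len[i], replace = TRUE, prob = prob), collapse = "")
  }, character(1))
}
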