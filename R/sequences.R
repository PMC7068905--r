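#' @importFrom Biostrings DNAStringSet DNAString reverseComplement GENETIC_CODE
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a nucleotide string
#'
#' Plain-character wrapper around [Biostrings::reverseComplement()]; `N`
#' bases are preserved.
#'
#' @param x single nucleotide string (A/C/G/T/N).
#' @return reverse-complemented string.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a nucleotide string with the standard genetic code
#'
#' Translates complete codons only; stop codons render as `*`. Codons
#' containing `N` translate to `X`.
#'
#' @param x nucleotide string, length need not be a multiple of 3 (the
#'   trailing partial codon is dropped).
#' @return amino-acid string.
#' @keywords internal
translate_nt <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return("")
  codons <- substring(x, seq(1L, by = 3L, length.out = n),
                      seq(3L, by = 3L, length.out = n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Validate a cDNA alphabet
#' @keywords internal
check_alphabet <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", seq))
    stop(what, " contains characters outside A/C/G/T/N", call. = FALSE)
  invisible(TRUE)
}
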