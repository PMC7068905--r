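#' Scan a 5' leader for upstream open reading frames
#'
#' Every occurrence of a start codon strictly 5' of the mORF start yields one
#' uORF; translation proceeds codon by codon from the start until the first
#' in-frame stop (TAA/TAG/TGA) anywhere on the transcript. Overlapping and
#' nested uORFs are all reported. uORF length counts start codon through stop
#' codon inclusive, so the minimal uORF (an AUG directly followed by a stop)
#' has length 6. `space3` is signed: negative values mean the uORF stop lies
#' 3' of the mORF start (Type2/Type3 overlap).
#'
#' @param spliced a `spliced_cdna` (reference or accession pseudo-cDNA).
#' @param start_codons character vector of 3-mers, default `"ATG"`.
#' @return data.frame, one row per uORF ordered by start offset, with columns
#'   `transcript_id`, `start` (0-based offset of the start codon's first
#'   base), `stop_end` (exclusive offset past the stop codon; `NA` when no
#'   in-frame stop exists before transcript end), `type` (Type1/Type2/Type3/
#'   unterminated), `length_nt`, `peptide` (stop excluded), `icc` (7-mer,
#'   N-padded), `kozak`, `space5`, `space3`, `start_codon`.
#' @export
find_uorfs <- function(spliced, start_codons = "ATG") {
  seq <- spliced$seq
  check_alphabet(seq, "cDNA")
  stopifnot(length(start_codons) >= 1L, all(nchar(start_codons) == 3L))
  n <- nchar(seq)
  morf_start <- spliced$morf_start
  empty <- empty_uorf_df()
  if (morf_start == 0L) return(empty)
  # candidate starts: vectorised 3-mer match anchored in the leader; the
  # start codon's first base must be 5' of the mORF start
  hi <- min(morf_start - 1L, n - 3L)
  if (hi < 0L) return(empty)
  lead_starts <- 0:hi
  trimers <- substring(seq, lead_starts + 1L, lead_starts + 3L)
  hits <- lead_starts[trimers %in% start_codons]
  if (!length(hits)) return(empty)
  rows <- lapply(hits, function(p) {
    stop_end <- scan_to_stop(seq, p)
    type <- classify_type(p, stop_end, morf_start, spliced$morf_end)
    len <- if (is.na(stop_end)) n - p else stop_end - p
    pep_end <- if (is.na(stop_end)) n else stop_end - 3L
    peptide <- translate_nt(substr(seq, p + 1L, pep_end))
    icc <- extract_icc(spliced, p)
    data.frame(transcript_id = spliced$transcript_id, start = p,
               stop_end = stop_end, type = type,
               length_nt = as.integer(len), peptide = peptide,
               icc = icc, kozak = is_kozak(icc),
               space5 = p,
               space3 = if (is.na(stop_end)) NA_integer_ else
                 as.integer(morf_start - stop_end),
               start_codon = substr(seq, p + 1L, p + 3L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

empty_uorf_df <- function() {
  data.frame(transcript_id = character(), start = integer(),
             stop_end = integer(), type = character(),
             length_nt = integer(), peptide = character(),
             icc = character(), kozak = logical(),
             space5 = integer(), space3 = integer(),
             start_codon = character(), stringsAsFactors = FALSE)
}

# first in-frame stop at/after offset p; returns exclusive end of the stop
# codon or NA if none before the transcript end
scan_to_stop <- function(seq, p) {
  n <- nchar(seq)
  if (p + 3L > n) return(NA_integer_)
  starts <- seq.int(p + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  hit <- which(codons %in% STOP_CODONS)
  if (!length(hit)) return(NA_integer_)
  as.integer(starts[hit[1L]] + 2L)
}

#' Classify a uORF by the position of its stop codon
#'
#' Type1: stop in the 5' leader. Type3: in frame with the mORF and sharing
#' its stop codon (an N-terminal extension). Type2: stop 3' of the mORF
#' start otherwise (for annotated transcripts, whose mORF has no internal
#' stop, this is exactly the out-of-frame overlap class). Unterminated uORFs
#' (no in-frame stop before transcript end) are reported but excluded from
#' type statistics downstream.
#'
#' @param start 0-based uORF start offset.
#' @param stop_end exclusive stop-codon end offset, or `NA`.
#' @param morf_start,morf_end mORF bounds on the cDNA (0-based, half-open).
#' @return one of "Type1", "Type2", "Type3", "unterminated".
#' @export
classify_type <- function(start, stop_end, morf_start, morf_end) {
  if (is.na(stop_end)) return("unterminated")
  if (stop_end <= morf_start) return("Type1")
  in_frame <- (morf_start - start) %% 3L == 0L
  if (in_frame && stop_end == morf_end) return("Type3")
  "Type2"
}

#' Extract the initiation codon context (ICC) around a start codon
#'
#' The 7-mer covering positions -3..+4 relative to the start codon (the A of
#' AUG is +1), N-padded where the window runs past either transcript edge.
#'
#' @param spliced a `spliced_cdna` (or any list with a `seq` field).
#' @param start 0-based offset of the start codon's first base.
#' @return 7-character string whose middle triplet is the codon at `start`.
#' @export
extract_icc <- function(spliced, start) {
  seq <- spliced$seq
  n <- nchar(seq)
  stopifnot(start >= 0L, start <= n - 3L)
  lo <- start - 3L; hi <- start + 4L        # [lo, hi), 0-based
  core <- substr(seq, max(lo, 0L) + 1L, min(hi, n))
  paste0(strrep("N", max(0L, -lo)), core, strrep("N", max(0L, hi - n)))
}

#' Test an ICC against the Kozak consensus
#'
#' Kozak consensus (A/G)CCAUGG: position -3 must be A or G, -2 and -1 must
#' be C, and +4 must be G. The middle triplet (the start codon itself) is
#' not constrained. N-padded positions fail.
#'
#' @param icc 7-mer from [extract_icc()].
#' @return logical.
#' @export
is_kozak <- function(icc) {
  stopifnot(nchar(icc) == 7L)
  b <- strsplit(icc, "")[[1L]]
  b[1L] %in% c("A", "G") && b[2L] == "C" && b[3L] == "C" && b[7L] == "G"
}

#' Three-way uORF type attribute of a gene model
#'
#' A model carrying at least one (AUG-initiated, terminated) Type2 uORF is
#' classed "Type2" even when Type1 uORFs coexist; a model with Type1 uORFs
#' only is "Type1-only"; otherwise "uORF-free". Type3 uORFs never change the
#' three-way class and are reported through the separate `has_type3` flag.
#'
#' @param uorfs data.frame from [find_uorfs()] for one splicing model.
#' @return list with `class` (uORF-free / Type1-only / Type2) and
#'   `has_type3` (logical).
#' @export
gene_type_attribute <- function(uorfs) {
  types <- uorfs$type[uorfs$type != "unterminated"]
  cls <- if (any(types == "Type2")) "Type2"
         else if (any(types == "Type1")) "Type1-only"
         else "uORF-free"
  list(class = cls, has_type3 = any(types == "Type3"))
}

#' Single-sequence uORF analysis from a cDNA and its CDS
#'
#' Locates the CDS within the cDNA by exact substring match (zero or multiple
#' matches are an error), then scans the implied 5' leader. This is the entry
#' point for custom analyses — species without a bundled annotation, or
#' non-AUG initiation codons supplied through `start_codons`.
#'
#' @param cdna cDNA sequence string, or path to a single-record FASTA.
#' @param cds CDS sequence string, or path to a single-record FASTA.
#' @param start_codons start-codon set, default `"ATG"`.
#' @param id transcript id used in the output.
#' @return data.frame as from [find_uorfs()].
#' @export
find_uorfs_single <- function(cdna, cds, start_codons = "ATG",
                              id = "query") {
  read1 <- function(x, what) {
    if (file.exists(x)) {
      ss <- Biostrings::readDNAStringSet(x)
      if (length(ss) != 1L) stop(what, " FASTA must contain one record")
      toupper(as.character(ss[[1L]]))
    } else toupper(x)
  }
  cdna <- read1(cdna, "cDNA"); cds <- read1(cds, "CDS")
  check_alphabet(cdna, "cDNA"); check_alphabet(cds, "CDS")
  hits <- gregexpr(cds, cdna, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) stop("CDS not found in cDNA")
  if (length(hits) > 1L) stop("ambiguous CDS placement: ", length(hits),
                              " exact matches in cDNA")
  morf_start <- as.integer(hits[1L]) - 1L
  sc <- structure(list(transcript_id = id, gene_id = id, seq = cdna,
                       morf_start = morf_start,
                       morf_end = morf_start + nchar(cds),
                       gmap = seq_len(nchar(cdna)) - 1L,
                       inserted = rep(FALSE, nchar(cdna)),
                       strand = "+", contig = id),
                  class = "spliced_cdna")
  find_uorfs(sc, start_codons)
}
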