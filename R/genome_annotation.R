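#' Load a reference genome from FASTA
#'
#' Reads a (multi-)FASTA into a named uppercase character vector, one element
#' per contig. Contig ids are taken as the first whitespace-delimited token
#' of each header.
#'
#' @param path FASTA file path.
#' @return named character vector of contig sequences (A/C/G/T/N).
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) stop("duplicate contig ids in FASTA")
  if (any(nchar(seqs) == 0L)) stop("empty contig sequence in FASTA")
  for (s in seqs) check_alphabet(s, "genome contig")
  seqs
}

#' Construct a transcript model
#'
#' A spliced gene model in 0-based half-open genomic coordinates. Exons must
#' be non-overlapping; the CDS (genomic span of coding exonic bases) must lie
#' within the exon union.
#'
#' @param gene_id,transcript_id identifiers.
#' @param contig contig id.
#' @param strand "+" or "-".
#' @param exons two-column matrix (start, end), 0-based half-open genomic.
#' @param cds_start,cds_end genomic bounds of the CDS, 0-based half-open.
#' @return object of class `transcript_model` with derived `leader_len`,
#'   `cds_len` (spliced) and `trailer_len`.
#' @export
transcript_model <- function(gene_id, transcript_id, contig, strand,
                             exons, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2L)
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
    stop("overlapping exons in transcript ", transcript_id)
  # per-base genomic coordinates of the mature transcript, 5'->3'
  gpos <- unlist(lapply(seq_len(nrow(exons)),
                        function(i) seq.int(exons[i, 1L], exons[i, 2L] - 1L)))
  if (strand == "-") gpos <- rev(gpos)
  in_cds <- gpos >= cds_start & gpos < cds_end
  if (!any(in_cds)) stop("CDS outside exons for transcript ", transcript_id)
  cds_idx <- which(in_cds)
  leader_len <- cds_idx[1L] - 1L
  cds_len <- length(cds_idx)
  structure(list(
    gene_id = gene_id, transcript_id = transcript_id, contig = contig,
    strand = strand, exons = exons,
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    leader_len = as.integer(leader_len), cds_len = as.integer(cds_len),
    trailer_len = length(gpos) - leader_len - cds_len,
    gpos = as.integer(gpos)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s, %d exon(s), leader %d nt, CDS %d nt\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), x$leader_len, x$cds_len))
  invisible(x)
}

#' Load gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS (and, when present, five_prime_UTR) features and
#' returns one `transcript_model` per mRNA. GFF3 coordinates (1-based
#' inclusive) are converted to the package's internal 0-based half-open
#' convention at this boundary. Transcripts whose spliced CDS length is not a
#' multiple of 3, is shorter than 6 nt, or whose CDS phase is non-zero are
#' excluded with a logged reason; transcripts with a zero-length leader are
#' retained but flagged.
#'
#' @param gff3 path to a GFF3 file.
#' @param genome named contig vector from [read_genome()] (used for bounds
#'   checks); may be `NULL` to skip the check.
#' @return list with `models` (named list of `transcript_model`),
#'   `no_leader` (character vector of transcript ids with leader length 0)
#'   and `excluded` (data.frame transcript_id, reason).
#' @export
load_annotation <- function(gff3, genome = NULL) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  df <- as.data.frame(gr)
  df$type <- as.character(df$type)
  df$strand <- as.character(df$strand)
  # GFF3 Parent may be a CharacterList
  parent <- if (is.null(df$Parent)) rep(NA_character_, nrow(df)) else
    vapply(df$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_, "")
  mrna <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  mrna_parent <- parent[df$type %in% c("mRNA", "transcript")]
  models <- list(); no_leader <- character(); excl <- list()
  for (i in seq_len(nrow(mrna))) {
    tx_id <- as.character(mrna$ID[i])
    gene_id <- if (!is.na(mrna_parent[i])) mrna_parent[i] else tx_id
    child <- df[!is.na(parent) & parent == tx_id, , drop = FALSE]
    ex <- child[child$type == "exon", , drop = FALSE]
    cds <- child[child$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L || nrow(cds) == 0L) {
      excl[[length(excl) + 1L]] <- data.frame(transcript_id = tx_id,
                                              reason = "missing exon or CDS features")
      next
    }
    if (!is.null(cds$phase)) {
      ph <- suppressWarnings(as.integer(as.character(cds$phase)))
      first <- if (mrna$strand[i] == "-") which.max(cds$end) else which.min(cds$start)
      if (!is.na(ph[first]) && ph[first] != 0L) {
        excl[[length(excl) + 1L]] <- data.frame(transcript_id = tx_id,
                                                reason = "CDS phase not 0")
        next
      }
    }
    exons <- cbind(ex$start - 1L, ex$end)      # to 0-based half-open
    cds_start <- min(cds$start) - 1L
    cds_end <- max(cds$end)
    if (!is.null(genome)) {
      contig <- as.character(mrna$seqnames[i])
      if (!contig %in% names(genome))
        stop("contig ", contig, " of transcript ", tx_id, " not in genome")
      if (max(exons[, 2L]) > nchar(genome[[contig]]))
        stop("exon exceeds contig bounds for transcript ", tx_id)
    }
    tm <- tryCatch(
      transcript_model(gene_id, tx_id, as.character(mrna$seqnames[i]),
                       mrna$strand[i], exons, cds_start, cds_end),
      error = function(e) e)
    if (inherits(tm, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(transcript_id = tx_id,
                                              reason = conditionMessage(tm))
      next
    }
    if (tm$cds_len %% 3L != 0L) {
      excl[[length(excl) + 1L]] <- data.frame(transcript_id = tx_id,
                                              reason = "CDS not multiple of 3")
      next
    }
    if (tm$cds_len < 6L) {
      excl[[length(excl) + 1L]] <- data.frame(transcript_id = tx_id,
                                              reason = "CDS shorter than 6 nt")
      next
    }
    # prefer annotated five_prime_UTR lengths for the leader when present
    utr5 <- child[child$type == "five_prime_UTR", , drop = FALSE]
    if (nrow(utr5) > 0L) {
      utr_len <- sum(utr5$end - utr5$start + 1L)
      if (utr_len != tm$leader_len)
        warning("five_prime_UTR length (", utr_len, ") disagrees with ",
                "exon/CDS geometry (", tm$leader_len, ") for ", tx_id,
                "; using geometry", call. = FALSE)
    }
    if (tm$leader_len == 0L) no_leader <- c(no_leader, tx_id)
    models[[tx_id]] <- tm
  }
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(transcript_id = character(), reason = character())
  list(models = models, no_leader = no_leader, excluded = excluded)
}

#' Select one representative splicing model per gene
#'
#' Chooses the transcript with the numerically smallest model suffix per
#' gene (e.g. ".1" over ".2"), honouring an optional override table.
#'
#' @param models named list of `transcript_model`.
#' @param override optional data.frame with columns `gene_id`,
#'   `transcript_id` taking precedence over suffix parsing.
#' @param suffix_pattern regular expression whose first capture group is the
#'   numeric model suffix; default accepts both "Gene.1" and "Gene.0.1"
#'   styles (the trailing number orders models in both).
#' @return list with `representative` (named list, one model per gene) and
#'   `excluded_genes` (data.frame gene_id, reason).
#' @export
select_representative <- function(models, override = NULL,
                                  suffix_pattern = "\\.([0-9]+)$") {
  by_gene <- split(models, vapply(models, `[[`, "", "gene_id"))
  rep_models <- list(); excl <- list()
  for (g in sort(names(by_gene))) {
    cand <- by_gene[[g]]
    if (!is.null(override) && g %in% override$gene_id) {
      want <- override$transcript_id[match(g, override$gene_id)]
      hit <- vapply(cand, function(m) m$transcript_id == want, TRUE)
      if (!any(hit)) {
        excl[[length(excl) + 1L]] <- data.frame(gene_id = g,
                                                reason = "override transcript not found")
        next
      }
      rep_models[[g]] <- cand[[which(hit)[1L]]]
      next
    }
    ids <- vapply(cand, `[[`, "", "transcript_id")
    m <- regmatches(ids, regexec(suffix_pattern, ids))
    suff <- suppressWarnings(vapply(m, function(x)
      if (length(x) >= 2L) as.numeric(x[2L]) else NA_real_, 0))
    if (all(is.na(suff))) {
      excl[[length(excl) + 1L]] <- data.frame(gene_id = g,
                                              reason = "no parsable model suffix")
      next
    }
    rep_models[[g]] <- cand[[which.min(suff)]]
  }
  list(representative = rep_models,
       excluded_genes = if (length(excl)) do.call(rbind, excl) else
         data.frame(gene_id = character(), reason = character()))
}

#' Build the spliced cDNA of a transcript
#'
#' Concatenates exon sequences in transcription order (reverse-complementing
#' minus-strand models) and records, for every cDNA base, its genomic anchor
#' on the forward strand of the reference. The mORF start offset equals the
#' leader length.
#'
#' @param tm a `transcript_model`.
#' @param genome named contig vector from [read_genome()].
#' @param start_codons start-codon set used only to warn when the reference
#'   mORF does not begin with one.
#' @return object of class `spliced_cdna`: fields `transcript_id`, `gene_id`,
#'   `seq`, `morf_start`, `morf_end` (0-based, half-open on the cDNA),
#'   `gmap` (integer genomic anchor per base), `inserted` (logical, all
#'   FALSE for reference), `strand`, `contig`.
#' @export
spliced_cdna <- function(tm, genome, start_codons = "ATG") {
  contig <- genome[[tm$contig]]
  if (is.null(contig)) stop("contig ", tm$contig, " not in genome")
  if (max(tm$exons[, 2L]) > nchar(contig))
    stop("exon exceeds contig bounds for transcript ", tm$transcript_id)
  fwd <- paste0(substring(contig, tm$exons[, 1L] + 1L, tm$exons[, 2L]),
                collapse = "")
  seq <- if (tm$strand == "-") revcomp(fwd) else fwd
  morf_start <- tm$leader_len
  morf_end <- tm$leader_len + tm$cds_len
  start <- substr(seq, morf_start + 1L, morf_start + 3L)
  if (!start %in% start_codons)
    warning("mORF of ", tm$transcript_id, " does not begin with a ",
            "configured start codon (", start, ")", call. = FALSE)
  structure(list(
    transcript_id = tm$transcript_id, gene_id = tm$gene_id,
    seq = seq, morf_start = as.integer(morf_start),
    morf_end = as.integer(morf_end),
    gmap = tm$gpos, inserted = rep(FALSE, nchar(seq)),
    strand = tm$strand, contig = tm$contig
  ), class = "spliced_cdna")
}

#' Convert between transcript and genome coordinates
#'
#' Uses the per-base anchor map of a spliced cDNA. Round trips are identity
#' on exonic bases; intronic/intergenic genomic positions map to `NA`.
#'
#' @param spliced a `spliced_cdna` (or accession pseudo-cDNA).
#' @param position 0-based position(s): cDNA offset for `to_genome`, forward
#'   genomic coordinate for `to_transcript`.
#' @param direction `"to_genome"` or `"to_transcript"`.
#' @return integer position(s); `NA` for non-exonic genomic input.
#' @export
map_coordinate <- function(spliced, position,
                           direction = c("to_genome", "to_transcript")) {
  direction <- match.arg(direction)
  position <- as.integer(position)
  if (direction == "to_genome") {
    if (any(position < 0L | position >= length(spliced$gmap)))
      stop("transcript offset out of range")
    spliced$gmap[position + 1L]
  } else {
    out <- match(position, spliced$gmap)
    as.integer(out - 1L)
  }
}
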