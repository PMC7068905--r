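#' Anchor a uORF in reference genome coordinates
#'
#' Returns the forward-strand reference coordinate of the first base of the
#' uORF start codon, read off the pseudo-cDNA offset map. Start codons whose
#' first base was created inside an insertion anchor to the insertion point
#' (the reference base 5' of the inserted run) and carry an insertion-origin
#' flag.
#'
#' @param pseudo a `spliced_cdna` or `pseudo_cdna`.
#' @param start 0-based start offset on the (pseudo-)cDNA.
#' @return list with `anchor` (integer genomic coordinate) and
#'   `insertion_origin` (logical).
#' @export
anchor_uorf <- function(pseudo, start) {
  stopifnot(start >= 0L, start < length(pseudo$gmap))
  list(anchor = pseudo$gmap[start + 1L],
       insertion_origin = pseudo$inserted[start + 1L])
}

#' Collect the uORF forms of one gene across accessions
#'
#' A form is a distinct (anchor, sequence) pair of a uORF observed on the
#' reference or on any accession pseudo-cDNA. Forms carry their length, the
#' uORF nucleotide sequence (start codon through stop codon), the causal
#' variant summary relative to the reference, and an origin class used for
#' identifier ordering: reference-identical and SNP-only forms rank before
#' deletion-bearing, which rank before insertion-bearing.
#'
#' @param ref_uorfs data.frame from [find_uorfs()] on the reference.
#' @param ref_spliced the reference `spliced_cdna`.
#' @param acc_results named list (by accession) of lists with elements
#'   `uorfs` (data.frame from [find_uorfs()]) and `pseudo` (the
#'   `pseudo_cdna` they were found on).
#' @return data.frame of forms: `anchor`, `length_nt`, `sequence`, `type`,
#'   `origin_class`, `n_snps`, `n_indels`, `snp_positions` / `var_positions`
#'   (comma strings), `variant_ids` (comma string), `insertion_origin`,
#'   `is_reference`, `accessions` (comma string of carriers; the reference
#'   itself is listed as "REF").
#' @export
collect_forms <- function(ref_uorfs, ref_spliced, acc_results) {
  forms <- new.env(parent = emptyenv())
  add <- function(anchor, seqnt, len, type, ins_origin, cv, is_ref, carrier) {
    key <- paste(anchor, seqnt, sep = "|")
    cur <- forms[[key]]
    if (is.null(cur)) {
      origin <- if (is_ref || (cv$n_snps + cv$n_indels) == 0L)
        "reference-identical"
      else if (any(cv$classes == "insertion")) "insertion-bearing"
      else if (any(cv$classes == "deletion")) "deletion-bearing"
      else "SNP-only"
      forms[[key]] <- list(anchor = anchor, length_nt = len,
                           sequence = seqnt, type = type,
                           origin_class = origin,
                           n_snps = cv$n_snps, n_indels = cv$n_indels,
                           snp_positions = sort(cv$positions[cv$classes == "SNP"]),
                           var_positions = cv$positions,
                           variant_ids = cv$variant_ids,
                           insertion_origin = ins_origin,
                           is_reference = is_ref, carriers = carrier)
    } else {
      cur$carriers <- c(cur$carriers, carrier)
      cur$is_reference <- cur$is_reference || is_ref
      if (is_ref) cur$origin_class <- "reference-identical"
      forms[[key]] <- cur
    }
  }
  uorf_seq <- function(cdna, start, stop_end) {
    end <- if (is.na(stop_end)) nchar(cdna$seq) else stop_end
    substr(cdna$seq, start + 1L, end)
  }
  empty_cv <- list(variant_ids = character(), n_snps = 0L, n_indels = 0L,
                   positions = integer(), classes = character())
  if (nrow(ref_uorfs)) for (i in seq_len(nrow(ref_uorfs))) {
    r <- ref_uorfs[i, ]
    if (r$type == "unterminated") next
    a <- anchor_uorf(ref_spliced, r$start)
    add(a$anchor, uorf_seq(ref_spliced, r$start, r$stop_end), r$length_nt,
        r$type, a$insertion_origin, empty_cv, TRUE, "REF")
  }
  for (acc in names(acc_results)) {
    res <- acc_results[[acc]]
    u <- res$uorfs
    if (!nrow(u)) next
    for (i in seq_len(nrow(u))) {
      r <- u[i, ]
      if (r$type == "unterminated") next
      a <- anchor_uorf(res$pseudo, r$start)
      cv <- causal_variants(res$pseudo, r$start, r$stop_end)
      add(a$anchor, uorf_seq(res$pseudo, r$start, r$stop_end), r$length_nt,
          r$type, a$insertion_origin, cv, FALSE, acc)
    }
  }
  keys <- ls(forms)
  if (!length(keys))
    return(data.frame(anchor = integer(), length_nt = integer(),
                      sequence = character(), type = character(),
                      origin_class = character(), n_snps = integer(),
                      n_indels = integer(), snp_positions = character(),
                      var_positions = character(), variant_ids = character(),
                      insertion_origin = logical(), is_reference = logical(),
                      accessions = character()))
  do.call(rbind, lapply(keys, function(k) {
    f <- forms[[k]]
    data.frame(anchor = f$anchor, length_nt = f$length_nt,
               sequence = f$sequence, type = f$type,
               origin_class = f$origin_class,
               n_snps = f$n_snps, n_indels = f$n_indels,
               snp_positions = paste(f$snp_positions, collapse = ","),
               var_positions = paste(f$var_positions, collapse = ","),
               variant_ids = paste(f$variant_ids, collapse = ","),
               insertion_origin = f$insertion_origin,
               is_reference = f$is_reference,
               accessions = paste(unique(f$carriers), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}

ORIGIN_RANK <- c("reference-identical" = 0L, "SNP-only" = 0L,
                 "deletion-bearing" = 1L, "insertion-bearing" = 2L)

#' Assign Level1.Level2 identifiers to the uORF forms of a gene
#'
#' Identifiers are continuous and start at 1.1. Level1 groups are the
#' distinct (anchor, length, origin class) triples — SNP-only forms share the
#' reference's Level1 class since substitutions are minor (Level2) variation.
#' Groups are numbered by anchor ascending, then length ascending (shorter
#' first), then origin class (reference/SNP-only before deletion-bearing
#' before insertion-bearing), then sorted causal-variant positions. Within a
#' group, forms take Level2 numbers by SNP count ascending, then sorted SNP
#' positions, then (as a documented stable tie-break) the form sequence.
#' Assignment is a pure function of the observed form set, so it is invariant
#' under accession input order.
#'
#' @param forms data.frame from [collect_forms()].
#' @return `forms` with added columns `level1`, `level2`, `identifier`
#'   ("L1.L2"), sorted in identifier order.
#' @export
assign_identifiers <- function(forms) {
  if (!nrow(forms)) {
    forms$level1 <- integer(); forms$level2 <- integer()
    forms$identifier <- character()
    return(forms)
  }
  rank <- ORIGIN_RANK[forms$origin_class]
  l1rank <- ifelse(rank == 0L, 0L, rank)
  gkey <- paste(forms$anchor, forms$length_nt, l1rank, sep = "|")
  # order Level1 groups by the composite key
  gdf <- unique(data.frame(key = gkey, anchor = forms$anchor,
                           length_nt = forms$length_nt, rank = l1rank,
                           stringsAsFactors = FALSE))
  gpos <- vapply(gdf$key, function(k)
    paste(sort(unique(forms$var_positions[gkey == k])), collapse = ","), "")
  ord <- order(gdf$anchor, gdf$length_nt, gdf$rank, gpos)
  level1_of <- stats::setNames(seq_along(ord), gdf$key[ord])
  forms$level1 <- as.integer(level1_of[gkey])
  forms$level2 <- NA_integer_
  for (g in unique(forms$level1)) {
    idx <- which(forms$level1 == g)
    o <- order(forms$n_snps[idx], forms$snp_positions[idx],
               forms$sequence[idx])
    forms$level2[idx[o]] <- seq_along(idx)
  }
  forms$identifier <- paste(forms$level1, forms$level2, sep = ".")
  forms[order(forms$level1, forms$level2), , drop = FALSE]
}

#' Classify per-accession uORF variant events at each locus
#'
#' Loci are reference anchors. For each accession and locus: an anchor
#' present only on the accession is a creation; only on the reference, a
#' loss; same anchor with different length, a length change; same anchor and
#' length with a different sequence, a substitution; identical, unchanged. A
#' type_switch event is additionally emitted whenever the uORF type at a
#' shared locus differs between reference and accession.
#'
#' @param ref_uorfs reference uORF data.frame (terminated rows used).
#' @param ref_spliced reference `spliced_cdna`.
#' @param acc_results named list as in [collect_forms()].
#' @return data.frame: `accession`, `anchor`, `event` (creation / loss /
#'   length_change / substitution / unchanged / type_switch), `from_type`,
#'   `to_type`.
#' @export
classify_events <- function(ref_uorfs, ref_spliced, acc_results) {
  ref_ok <- ref_uorfs[ref_uorfs$type != "unterminated", , drop = FALSE]
  ref_loci <- if (nrow(ref_ok)) data.frame(
    anchor = vapply(ref_ok$start, function(s)
      anchor_uorf(ref_spliced, s)$anchor, 0L),
    length_nt = ref_ok$length_nt, type = ref_ok$type,
    sequence = vapply(seq_len(nrow(ref_ok)), function(i)
      substr(ref_spliced$seq, ref_ok$start[i] + 1L, ref_ok$stop_end[i]), ""),
    stringsAsFactors = FALSE) else
    data.frame(anchor = integer(), length_nt = integer(),
               type = character(), sequence = character())
  out <- list()
  emit <- function(acc, anchor, event, from = NA_character_,
                   to = NA_character_)
    out[[length(out) + 1L]] <<- data.frame(
      accession = acc, anchor = anchor, event = event,
      from_type = from, to_type = to, stringsAsFactors = FALSE)
  for (acc in names(acc_results)) {
    res <- acc_results[[acc]]
    u <- res$uorfs[res$uorfs$type != "unterminated", , drop = FALSE]
    acc_loci <- if (nrow(u)) data.frame(
      anchor = vapply(u$start, function(s)
        anchor_uorf(res$pseudo, s)$anchor, 0L),
      length_nt = u$length_nt, type = u$type,
      sequence = vapply(seq_len(nrow(u)), function(i)
        substr(res$pseudo$seq, u$start[i] + 1L, u$stop_end[i]), ""),
      stringsAsFactors = FALSE) else ref_loci[0, ]
    for (a in union(ref_loci$anchor, acc_loci$anchor)) {
      r <- ref_loci[ref_loci$anchor == a, , drop = FALSE]
      q <- acc_loci[acc_loci$anchor == a, , drop = FALSE]
      if (!nrow(r)) {
        emit(acc, a, "creation", to = q$type[1L])
      } else if (!nrow(q)) {
        emit(acc, a, "loss", from = r$type[1L])
      } else if (r$length_nt[1L] != q$length_nt[1L]) {
        emit(acc, a, "length_change", from = r$type[1L], to = q$type[1L])
      } else if (r$sequence[1L] != q$sequence[1L]) {
        emit(acc, a, "substitution", from = r$type[1L], to = q$type[1L])
      } else {
        emit(acc, a, "unchanged", from = r$type[1L], to = q$type[1L])
      }
      if (nrow(r) && nrow(q) && r$type[1L] != q$type[1L])
        emit(acc, a, "type_switch", from = r$type[1L], to = q$type[1L])
    }
  }
  if (!length(out)) return(data.frame(accession = character(),
                                      anchor = integer(), event = character(),
                                      from_type = character(),
                                      to_type = character()))
  do.call(rbind, out)
}
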