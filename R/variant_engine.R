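#' Read and quality-filter variants from a multi-sample VCF
#'
#' Keeps records whose FILTER is PASS or ".", splits multi-allelic records
#' into one biallelic record per ALT allele, and classifies each as SNP,
#' insertion, deletion or MNP. Per-sample genotypes travel with each record:
#' a sample carries an allele only when homozygous for it, and — when the AD
#' (allele depth) FORMAT field is present — only when the supporting-read
#' fraction for that allele is at least `af_threshold`.
#'
#' @param vcf path to a VCF v4.x file with GT (and optionally AD) genotypes.
#' @param af_threshold minimum per-sample supporting-read fraction when AD is
#'   available (default 0.90); a no-op without AD.
#' @return list with `variants` (data.frame: variant_id, contig, pos
#'   (0-based), ref, alt, class) and `genotypes` (logical matrix, variants x
#'   samples, TRUE where the sample is a kept homozygous-alternate call).
#' @export
read_variants <- function(vcf, af_threshold = 0.90) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  ad_raw <- if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID)
    vcfR::extract.gt(v, element = "AD") else NULL
  samples <- colnames(gt_raw)
  keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  rows <- list(); gts <- list()
  for (i in which(keep)) {
    ref <- toupper(fix$REF[i])
    alts <- strsplit(toupper(fix$ALT[i]), ",", fixed = TRUE)[[1L]]
    pos0 <- as.integer(fix$POS[i]) - 1L              # to 0-based
    if (is.na(pos0) || is.na(ref) || !nzchar(ref))
      stop("malformed VCF record at line for ", fix$CHROM[i], ":", fix$POS[i])
    gt <- gt_raw[i, ]
    ad <- if (!is.null(ad_raw)) ad_raw[i, ] else NULL
    for (k in seq_along(alts)) {
      alt <- alts[k]
      if (alt == ref || alt %in% c(".", "*", "")) next
      id <- fix$ID[i]
      if (is.na(id) || id == ".")
        id <- paste(fix$CHROM[i], fix$POS[i], ref, alt, sep = ":")
      else if (length(alts) > 1L) id <- paste0(id, "_", k)
      hom <- vapply(seq_along(gt), function(j) {
        g <- gt[j]
        if (is.na(g)) return(FALSE)
        al <- strsplit(g, "[/|]")[[1L]]
        if (!all(al == as.character(k))) return(FALSE)
        if (!is.null(ad) && !is.na(ad[j])) {
          d <- suppressWarnings(as.numeric(strsplit(ad[j], ",")[[1L]]))
          tot <- sum(d, na.rm = TRUE)
          if (tot > 0 && length(d) > k &&
              !is.na(d[k + 1L]) && d[k + 1L] / tot < af_threshold)
            return(FALSE)
        }
        TRUE
      }, TRUE)
      cls <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNP"
             else if (nchar(ref) > nchar(alt)) "deletion"
             else if (nchar(ref) < nchar(alt)) "insertion"
             else "MNP"
      rows[[length(rows) + 1L]] <- data.frame(
        variant_id = id, contig = fix$CHROM[i], pos = pos0,
        ref = ref, alt = alt, class = cls, stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- hom
    }
  }
  variants <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant_id = character(), contig = character(),
               pos = integer(), ref = character(), alt = character(),
               class = character())
  genotypes <- if (length(gts)) do.call(rbind, gts) else
    matrix(logical(), 0L, length(samples))
  colnames(genotypes) <- samples
  rownames(genotypes) <- variants$variant_id
  list(variants = variants, genotypes = genotypes)
}

#' Homozygous variant set of one accession on one transcript
#'
#' Restricts filtered variants to those the accession carries homozygously
#' and whose reference span lies within the transcript's exonic leader+CDS
#' region (variants 3' of the mORF stop cannot alter uORFs and are ignored).
#' Variants overlapping a splice junction or only partly exonic are skipped
#' with a warning; of two variants with overlapping reference spans the
#' 5'-most (in mRNA orientation) is kept.
#'
#' @param vset list from [read_variants()].
#' @param accession sample id.
#' @param spliced reference `spliced_cdna` of the transcript.
#' @return data.frame of variants (columns as in `vset$variants` plus
#'   `tx_start`, `tx_end`: the replaced transcript span, 0-based half-open,
#'   and `ref_tx`, `alt_tx`: alleles in mRNA orientation), sorted by
#'   `tx_start`.
#' @export
accession_variants <- function(vset, accession, spliced) {
  stopifnot(accession %in% colnames(vset$genotypes))
  hom <- vset$genotypes[, accession]
  v <- vset$variants[hom & vset$variants$contig == spliced$contig, ,
                     drop = FALSE]
  if (!nrow(v)) return(cbind(v, tx_start = integer(), tx_end = integer(),
                             ref_tx = character(), alt_tx = character()))
  span_end <- spliced$morf_end                    # exonic leader+CDS only
  out <- list()
  for (i in seq_len(nrow(v))) {
    gspan <- v$pos[i] + seq_len(nchar(v$ref[i])) - 1L
    tx <- match(gspan, spliced$gmap) - 1L
    if (any(is.na(tx))) {
      if (!all(is.na(tx)))
        warning("variant ", v$variant_id[i],
                " overlaps a splice junction; skipped", call. = FALSE)
      next
    }
    if (spliced$strand == "-") tx <- rev(tx)
    if (any(diff(tx) != 1L)) {
      warning("variant ", v$variant_id[i],
              " spans non-contiguous transcript bases; skipped",
              call. = FALSE)
      next
    }
    if (tx[1L] >= span_end) next                  # 3' of the mORF stop
    ref_tx <- if (spliced$strand == "-") revcomp(v$ref[i]) else v$ref[i]
    alt_tx <- if (spliced$strand == "-") revcomp(v$alt[i]) else v$alt[i]
    out[[length(out) + 1L]] <- cbind(v[i, , drop = FALSE],
      data.frame(tx_start = tx[1L], tx_end = tx[length(tx)] + 1L,
                 ref_tx = ref_tx, alt_tx = alt_tx,
                 stringsAsFactors = FALSE))
  }
  if (!length(out)) return(cbind(v[0, , drop = FALSE],
                                 tx_start = integer(), tx_end = integer(),
                                 ref_tx = character(), alt_tx = character()))
  av <- do.call(rbind, out)
  av <- av[order(av$tx_start), , drop = FALSE]
  # overlapping reference spans: keep the 5'-most, skip the rest
  keep <- rep(TRUE, nrow(av)); last_end <- -1L
  for (i in seq_len(nrow(av))) {
    if (av$tx_start[i] < last_end) {
      warning("variant ", av$variant_id[i], " overlaps an earlier variant; ",
              "skipped", call. = FALSE)
      keep[i] <- FALSE
    } else last_end <- max(last_end, av$tx_end[i])
  }
  rownames(av) <- NULL
  av[keep, , drop = FALSE]
}

#' Screen a gene for variants hitting the mORF start codon
#'
#' The mORF initiation codon is the fixed coordinate anchoring all uORF
#' comparisons; a gene is dropped for an accession whose variants intersect
#' any of the three (spliced-aware) genomic bases of that codon.
#'
#' @param spliced reference `spliced_cdna`.
#' @param av accession variant data.frame from [accession_variants()].
#' @return TRUE to keep, FALSE to drop.
#' @export
screen_morf_start <- function(spliced, av) {
  if (!nrow(av)) return(TRUE)
  codon_g <- spliced$gmap[spliced$morf_start + 1:3]
  for (i in seq_len(nrow(av))) {
    gspan <- av$pos[i] + seq_len(nchar(av$ref[i])) - 1L
    if (any(gspan %in% codon_g)) return(FALSE)
  }
  TRUE
}

#' Build an accession pseudo-cDNA by applying its variants
#'
#' Applies substitutions and indels in descending transcript-offset order so
#' earlier offsets stay valid. Alongside the mutated sequence it maintains a
#' per-base reference genomic anchor map: substituted bases keep their
#' anchors; inserted bases anchor to the reference base immediately 5' (in
#' mRNA orientation) of the insertion point and are flagged inserted. The
#' mORF start offset is shifted by the summed indel deltas 5' of it.
#'
#' @param spliced reference `spliced_cdna`.
#' @param av accession variant data.frame from [accession_variants()].
#' @param accession accession id recorded on the result.
#' @return a `pseudo_cdna`: a `spliced_cdna` with additional fields
#'   `accession`, `applied` (data.frame of applied variants with their
#'   pseudo-space start offsets) and updated `seq`, `morf_start`, `morf_end`,
#'   `gmap`, `inserted`.
#' @export
build_pseudo_cdna <- function(spliced, av, accession = NA_character_) {
  seq <- spliced$seq
  gmap <- spliced$gmap
  ins <- spliced$inserted
  morf_start <- spliced$morf_start
  morf_end <- spliced$morf_end
  applied <- av[0, , drop = FALSE]
  pseudo_start <- integer()
  if (nrow(av)) {
    ord <- order(av$tx_start, decreasing = TRUE)
    for (i in ord) {
      a <- av$tx_start[i]; b <- av$tx_end[i]
      ref_tx <- av$ref_tx[i]; alt_tx <- av$alt_tx[i]
      stopifnot(substr(seq, a + 1L, b) == ref_tx)
      L <- nchar(alt_tx); n <- b - a
      seq <- paste0(substr(seq, 1L, a), alt_tx,
                    substring(seq, b + 1L))
      old_anchor <- gmap[(a + 1L):b]
      old_ins <- ins[(a + 1L):b]
      if (spliced$strand == "-") {
        idx <- pmax(1L, n - L + seq_len(L))   # suffix: anchor base is 3'-most
      } else {
        idx <- pmin(seq_len(L), n)            # prefix: anchor base is 5'-most
      }
      new_anchor <- old_anchor[idx]
      new_ins <- old_ins[idx] | (if (spliced$strand == "-")
        seq_len(L) <= L - n else seq_len(L) > n)
      gmap <- c(gmap[seq_len(a)], new_anchor, gmap[seq.int(b + 1L,
                length.out = length(gmap) - b)])
      ins <- c(ins[seq_len(a)], new_ins, ins[seq.int(b + 1L,
               length.out = length(ins) - b)])
      delta <- L - n
      if (b <= morf_start) morf_start <- morf_start + delta
      if (b <= morf_end) morf_end <- morf_end + delta
      applied <- rbind(av[i, , drop = FALSE], applied)
      pseudo_start <- c(a, pseudo_start)
    }
    # pseudo-space offsets of earlier edits shift by downstream-applied
    # deltas 5' of them: recompute by replaying in ascending order
    deltas <- nchar(applied$alt_tx) - (applied$tx_end - applied$tx_start)
    shift <- c(0L, cumsum(deltas))[seq_len(nrow(applied))]
    pseudo_start <- applied$tx_start + shift
  }
  structure(list(
    transcript_id = spliced$transcript_id, gene_id = spliced$gene_id,
    accession = accession, seq = seq,
    morf_start = as.integer(morf_start), morf_end = as.integer(morf_end),
    gmap = as.integer(gmap), inserted = ins,
    strand = spliced$strand, contig = spliced$contig,
    applied = cbind(applied,
                    data.frame(pseudo_start = as.integer(pseudo_start)))
  ), class = c("pseudo_cdna", "spliced_cdna"))
}

#' Undo an accession's edits on its pseudo-cDNA
#'
#' Replays the applied edits inversely (alt back to ref) in descending
#' pseudo-offset order; used to verify edit bookkeeping.
#'
#' @param pseudo a `pseudo_cdna`.
#' @return the reconstructed reference cDNA sequence string.
#' @export
invert_pseudo_cdna <- function(pseudo) {
  seq <- pseudo$seq
  ap <- pseudo$applied
  if (nrow(ap)) for (i in order(ap$pseudo_start, decreasing = TRUE)) {
    a <- ap$pseudo_start[i]
    L <- nchar(ap$alt_tx[i])
    stopifnot(substr(seq, a + 1L, a + L) == ap$alt_tx[i])
    seq <- paste0(substr(seq, 1L, a), ap$ref_tx[i], substring(seq, a + L + 1L))
  }
  seq
}

#' Causal variants of a uORF form
#'
#' The applied variants whose reference genomic spans intersect the uORF's
#' reference-anchored interval (start codon through stop codon). For created
#' or lost uORFs the interval is taken over the bases forming (or formerly
#' forming) the start/stop codons, which the anchor map covers.
#'
#' @param pseudo the `pseudo_cdna` carrying the uORF.
#' @param start,stop_end uORF bounds on the pseudo-cDNA (0-based half-open);
#'   `stop_end` may be `NA` for unterminated uORFs (interval runs to the
#'   transcript end).
#' @return list with `variant_ids`, `n_snps`, `n_indels`, `positions`
#'   (sorted 0-based genomic positions of the causal variants) and `classes`.
#' @export
causal_variants <- function(pseudo, start, stop_end) {
  ap <- pseudo$applied
  if (is.null(ap) || !nrow(ap))
    return(list(variant_ids = character(), n_snps = 0L, n_indels = 0L,
                positions = integer(), classes = character()))
  end <- if (is.na(stop_end)) length(pseudo$gmap) else stop_end
  anchors <- pseudo$gmap[(start + 1L):end]
  lo <- min(anchors); hi <- max(anchors)
  hit <- vapply(seq_len(nrow(ap)), function(i) {
    gspan <- ap$pos[i] + c(0L, nchar(ap$ref[i]) - 1L)
    gspan[2L] >= lo && gspan[1L] <= hi
  }, TRUE)
  v <- ap[hit, , drop = FALSE]
  list(variant_ids = v$variant_id,
       n_snps = sum(v$class == "SNP"),
       n_indels = sum(v$class %in% c("insertion", "deletion")),
       positions = sort(v$pos),
       classes = v$class)
}
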