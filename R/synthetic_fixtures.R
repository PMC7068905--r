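#' @title Synthetic fixture universes
#' @description Deterministic generator of self-contained test universes:
#'   genome FASTA, GFF3 annotation, multi-sample VCF, accession metadata and
#'   a machine-readable truth table with planted uORFs and planted variant
#'   events. Leaders are assembled from verified uORF building blocks
#'   embedded in start-codon-free padding (padding is drawn from C/T/G with a
#'   C at block junctions, so no ATG can arise outside a planted block).
#'   All randomness is integer-draw based and fully determined by the seed.
#' @name synthetic_fixtures
NULL

# padding that can never contain or help form an ATG (no A at all);
# first base fixed to C so block/pad junctions cannot form ATG either
pad_seq <- function(n) {
  if (n <= 0L) return("")
  paste0(c("C", c("C", "T", "G")[sample.int(3L, n - 1L, replace = TRUE)]),
         collapse = "")
}

# integer-draw Bernoulli
coin <- function(p) sample.int(1000000L, 1L) <= round(p * 1000000L)

# Planted leader scenarios. `block` sits mid-leader (Type1 / creation
# sites); `tail` abuts the CDS (overlap types). Event edits are transcript
# space, anchored at the locus start; ref/alt share their first base for
# indels. Every event is the minimal variant set realizing it.
.scenarios <- list(
  t1 = list(                       # Type1 uORF "ATG AAA AAA TAA"
    block = "ATGAAAAAATAA", tail = "", ref_uorf = TRUE, type = "Type1",
    attr = "Type1-only",
    events = list(
      loss = list(edits = list(list(off = 1L, ref = "T", alt = "C")),
                  form = NULL, attr = "uORF-free"),
      substitution = list(edits = list(list(off = 4L, ref = "A", alt = "G"),
                                       list(off = 7L, ref = "A", alt = "G")),
                          form = list(len = 12L, rank = 0L, n_snps = 2L),
                          attr = "Type1-only"),
      length_change_del = list(edits = list(list(off = 2L, ref = "GAAA",
                                                 alt = "G")),
                               form = list(len = 9L, rank = 1L, n_snps = 0L),
                               attr = "Type1-only"),
      length_change_ins = list(edits = list(list(off = 2L, ref = "G",
                                                 alt = "GAAA")),
                               form = list(len = 15L, rank = 2L,
                                           n_snps = 0L),
                               attr = "Type1-only"))),
  t2 = list(                       # Type2: leader tail ATGC runs into CDS
    block = "", tail = "ATGC", ref_uorf = TRUE, type = "Type2",
    attr = "Type2",
    events = list(
      loss = list(edits = list(list(off = 1L, ref = "T", alt = "C")),
                  form = NULL, attr = "uORF-free"),
      substitution = list(edits = list(list(off = 3L, ref = "C",
                                            alt = "G")),
                          form = list(len = 12L, rank = 0L, n_snps = 1L),
                          attr = "Type2"))),
  t3 = list(                       # Type3: in-frame N-extension
    block = "", tail = "ATGGCAGCA", ref_uorf = TRUE, type = "Type3",
    attr = "uORF-free",            # Type3 never changes the three-way class
    events = list(
      loss = list(edits = list(list(off = 1L, ref = "T", alt = "C")),
                  form = NULL, attr = "uORF-free"))),
  free = list(                     # no uORF; ACG one SNP away from ATG
    block = "ACGAAATAA", tail = "", ref_uorf = FALSE, type = NA_character_,
    attr = "uORF-free",
    events = list(
      creation = list(edits = list(list(off = 1L, ref = "C", alt = "T")),
                      form = list(len = 9L, rank = 0L, n_snps = 1L),
                      attr = "Type1-only"))),
  switch = list(                   # Type1 whose stop loss makes it Type2
    block = "", tail = "ATGTGAC", ref_uorf = TRUE, type = "Type1",
    attr = "Type1-only",
    events = list(
      type_switch = list(edits = list(list(off = 5L, ref = "A",
                                           alt = "C")),
                         form = list(len = 15L, rank = 0L, n_snps = 1L),
                         attr = "Type2")))
)

# reference uORF length per scenario (NA when the reference has none)
scenario_ref_len <- function(scenario, cds_len)
  switch(scenario, t1 = 12L, t2 = 12L, t3 = 9L + cds_len,
         free = NA_integer_, switch = 6L)

# CDS used by all fixture genes; the ATGCTTGAT prefix supplies the
# out-of-frame stop that terminates Type2/switched uORFs; GGT filler has no
# in-frame stop
fixture_cds <- function(n_filler = 6L)
  paste0("ATGCTTGAT", strrep("GGT", n_filler), "TGA")

# per-base genomic coordinates of a spliced transcript, 5'->3'
gpos_from_exons <- function(exons, strand) {
  gp <- unlist(lapply(seq_len(nrow(exons)),
                      function(i) seq.int(exons[i, 1L], exons[i, 2L] - 1L)))
  if (strand == "-") rev(gp) else gp
}

#' Default fixture configuration
#'
#' @param n_genes number of genes (scenarios t1/t2/t3/free/switch cycle).
#' @param n_accessions number of accessions in the VCF.
#' @param seed integer seed; fully determines every output byte.
#' @param event_rate probability that an accession carries a given planted
#'   event (events of one gene are mutually exclusive per accession so the
#'   truth table stays exact).
#' @param distractor_rate probability of adding, per gene, a heterozygous
#'   and a FILTER-failing distractor record.
#' @param pad5,pad3 padding lengths 5' of the planted blocks and in the
#'   3' UTR.
#' @return config list.
#' @export
fixture_config <- function(n_genes = 10L, n_accessions = 20L, seed = 1L,
                           event_rate = 0.15, distractor_rate = 0.5,
                           pad5 = 30L, pad3 = 15L) {
  stopifnot(event_rate >= 0, event_rate <= 0.25, n_genes >= 1L,
            n_accessions >= 1L)
  list(n_genes = as.integer(n_genes),
       n_accessions = as.integer(n_accessions), seed = as.integer(seed),
       event_rate = event_rate, distractor_rate = distractor_rate,
       pad5 = as.integer(pad5), pad3 = as.integer(pad3))
}

#' Generate a synthetic fixture universe
#'
#' Writes `genome.fa`, `annotation.gff3`, `variants.vcf`, `metadata.tsv` and
#' `truth.json` under `out_dir` and returns the truth table. Genes alternate
#' strand and exon count (1-3); introns are placed inside padding or the CDS
#' filler, never through a planted block. Scenario `t1` genes get a second
#' splicing model (suffix .2) whose leader starts 3' of the planted uORF, so
#' splicing-model type transitions are exercised.
#'
#' @param config from [fixture_config()].
#' @param out_dir output directory (created if needed).
#' @return invisible truth list: `config`, `accessions`, `genes` (per gene:
#'   scenario, contig, strand, transcript ids, locus anchor, reference uORF
#'   type/length, planted event table), `assignments` (per gene: accession ->
#'   expected identifier or "absent"), `attributes` (per gene: reference and
#'   per-accession expected three-way attribute), `metadata`.
#' @export
generate_fixture <- function(config = fixture_config(), out_dir) {
  set.seed(config$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  acc_ids <- sprintf("acc%03d", seq_len(config$n_accessions))
  scen_names <- rep(names(.scenarios), length.out = config$n_genes)
  fasta <- character(); gff <- "##gff-version 3"; vcf_rows <- list()
  truth_genes <- list(); assignments <- list(); attributes <- list()
  cds <- fixture_cds()
  for (g in seq_len(config$n_genes)) {
    scen <- scen_names[g]
    sc <- .scenarios[[scen]]
    strand <- if (g %% 2L == 1L) "+" else "-"
    n_exons <- ((g - 1L) %% 3L) + 1L
    gene_id <- sprintf("GENE%02d", g)
    tx_id <- paste0(gene_id, ".1")
    contig <- sprintf("chr%02d", g)
    pad1 <- pad_seq(config$pad5)
    pad2 <- if (nzchar(sc$block)) pad_seq(12L) else ""
    leader <- paste0(pad1, sc$block, pad2, sc$tail)
    trailer <- pad_seq(config$pad3)
    cdna <- paste0(leader, cds, trailer)
    morf_start <- nchar(leader)
    locus_start <- if (nzchar(sc$block)) nchar(pad1) else
      nchar(pad1) + nchar(pad2)                  # tx offset of the locus
    # exon cut points sit inside pad1 / CDS filler, away from blocks
    cuts <- integer()
    if (n_exons >= 2L) cuts <- c(cuts, morf_start + 12L +
                                   3L * sample.int(4L, 1L))
    if (n_exons >= 3L) cuts <- c(cuts, 5L + sample.int(10L, 1L))
    cuts <- sort(cuts)
    bounds <- c(0L, cuts, nchar(cdna))
    pieces <- substring(cdna, bounds[-length(bounds)] + 1L, bounds[-1L])
    introns <- if (length(pieces) > 1L)
      vapply(seq_len(length(pieces) - 1L),
             function(i) pad_seq(20L + sample.int(15L, 1L)), "") else
      character()
    gseq <- paste0(pieces, c(introns, ""), collapse = "")
    np <- nchar(pieces)
    ex_start <- cumsum(c(0L, np[-length(np)] + nchar(introns)))
    ex <- cbind(ex_start, ex_start + np)
    flank <- 20L
    if (strand == "-") {
      L <- nchar(gseq)
      contig_seq <- paste0(pad_seq(flank), revcomp(gseq), pad_seq(flank))
      exons <- cbind(flank + L - ex[, 2L], flank + L - ex[, 1L])
      exons <- exons[order(exons[, 1L]), , drop = FALSE]
    } else {
      contig_seq <- paste0(pad_seq(flank), gseq, pad_seq(flank))
      exons <- ex + flank
    }
    gpos <- gpos_from_exons(exons, strand)
    cds_g <- range(gpos[(morf_start + 1L):(morf_start + nchar(cds))])
    tm <- transcript_model(gene_id, tx_id, contig, strand, exons,
                           cds_g[1L], cds_g[2L] + 1L)
    stopifnot(tm$leader_len == morf_start, tm$cds_len == nchar(cds))
    fasta <- c(fasta, paste0(">", contig), contig_seq)
    gff <- c(gff,
      sprintf("%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              contig, min(exons[, 1L]) + 1L, max(exons[, 2L]), strand,
              gene_id),
      gff_mrna(contig, strand, exons, tx_id, gene_id, morf_start,
               nchar(cds), gpos))
    tx2 <- NULL
    if (scen == "t1") {          # second splicing model, uORF spliced out
      tx2 <- paste0(gene_id, ".2")
      trim <- locus_start + nchar(sc$block) + 2L
      gpos2 <- gpos[-seq_len(trim)]
      exons2 <- collapse_runs(sort(gpos2))
      tm2 <- transcript_model(gene_id, tx2, contig, strand, exons2,
                              cds_g[1L], cds_g[2L] + 1L)
      gff <- c(gff, gff_mrna(contig, strand, exons2, tx2, gene_id,
                             tm2$leader_len, nchar(cds), tm2$gpos))
    }
    # each accession draws at most one event for this gene
    ev_names <- names(sc$events)
    draw <- sample.int(length(ev_names) + 1L, config$n_accessions,
                       replace = TRUE,
                       prob = c(rep(config$event_rate, length(ev_names)),
                                1 - config$event_rate * length(ev_names)))
    truth_events <- list()
    for (k in seq_along(ev_names)) {
      ev <- ev_names[k]
      carriers <- acc_ids[draw == k]
      ids <- character()
      for (e in sc$events[[ev]]$edits) {
        rec <- tx_edit_to_vcf(tm, contig_seq, locus_start + e$off,
                              e$ref, e$alt)
        rec$id <- sprintf("%s_%s_%d", gene_id, ev, e$off)
        rec$gt <- ifelse(acc_ids %in% carriers, "1/1", "0/0")
        vcf_rows[[length(vcf_rows) + 1L]] <- rec
        ids <- c(ids, rec$id)
      }
      truth_events[[ev]] <- list(accessions = carriers, variant_ids = ids,
                                 n_edits = length(sc$events[[ev]]$edits))
    }
    if (coin(config$distractor_rate)) {
      for (filt in c("het", "lowqual")) {
        p <- 3L + sample.int(10L, 1L)
        ref <- substr(cdna, p + 1L, p + 1L)
        alt <- setdiff(c("C", "T", "G"), ref)[sample.int(2L, 1L)]
        rec <- tx_edit_to_vcf(tm, contig_seq, p, ref, alt)
        rec$id <- sprintf("%s_distractor_%s", gene_id, filt)
        if (filt == "het") {
          rec$gt <- ifelse(seq_along(acc_ids) %% 3L == 0L, "0/1", "0/0")
        } else {
          rec$gt <- rep("1/1", length(acc_ids))
          rec$filter <- "LowQual"
        }
        vcf_rows[[length(vcf_rows) + 1L]] <- rec
      }
    }
    ids <- expected_identifiers(scen, sc, truth_events, nchar(cds))
    gene_assign <- expected_assignments(sc, truth_events, ids, acc_ids)
    truth_genes[[gene_id]] <- list(
      scenario = scen, contig = contig, strand = strand,
      transcript_id = tx_id, transcript_id2 = tx2,
      locus_tx_start = locus_start,
      locus_anchor = gpos[locus_start + 1L],
      ref_uorf = sc$ref_uorf, uorf_type = sc$type,
      ref_uorf_len = scenario_ref_len(scen, nchar(cds)),
      morf_start = morf_start,
      events = truth_events,
      splicing_attr2 = if (!is.null(tx2)) "uORF-free" else NULL)
    assignments[[gene_id]] <- gene_assign$identifier
    attributes[[gene_id]] <- list(reference = sc$attr,
                                  accession = gene_assign$attribute)
  }
  writeLines(fasta, file.path(out_dir, "genome.fa"))
  writeLines(gff, file.path(out_dir, "annotation.gff3"))
  write_fixture_vcf(vcf_rows, acc_ids, file.path(out_dir, "variants.vcf"))
  lat <- (sample.int(1351L, length(acc_ids), replace = TRUE) - 601L) / 10
  metadata <- data.frame(accession_id = acc_ids, latitude = lat,
                         group_label = ifelse(seq_along(acc_ids) %% 2L == 0L,
                                              "grpA", "grpB"))
  utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(config = config, accessions = acc_ids, genes = truth_genes,
                assignments = assignments, attributes = attributes,
                metadata = metadata)
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

# contiguous runs of sorted genomic positions -> half-open exon matrix
collapse_runs <- function(x) {
  br <- c(0L, which(diff(x) != 1L), length(x))
  t(vapply(seq_len(length(br) - 1L), function(i)
    c(x[br[i] + 1L], x[br[i + 1L]] + 1L), integer(2L)))
}

gff_mrna <- function(contig, strand, exons, tx_id, gene_id,
                     leader_len, cds_len, gpos) {
  lines <- sprintf("%s\tfixture\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                   contig, min(exons[, 1L]) + 1L, max(exons[, 2L]), strand,
                   tx_id, gene_id)
  for (i in seq_len(nrow(exons)))
    lines <- c(lines,
               sprintf("%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                       contig, exons[i, 1L] + 1L, exons[i, 2L], strand,
                       tx_id))
  cds_ex <- collapse_runs(sort(gpos[(leader_len + 1L):(leader_len + cds_len)]))
  ord <- if (strand == "-") rev(seq_len(nrow(cds_ex))) else
    seq_len(nrow(cds_ex))
  done <- 0L
  for (i in ord) {
    phase <- (3L - done %% 3L) %% 3L
    lines <- c(lines,
               sprintf("%s\tfixture\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                       contig, cds_ex[i, 1L] + 1L, cds_ex[i, 2L], strand,
                       phase, tx_id))
    done <- done + cds_ex[i, 2L] - cds_ex[i, 1L]
  }
  if (leader_len > 0L) {
    utr <- collapse_runs(sort(gpos[seq_len(leader_len)]))
    for (i in seq_len(nrow(utr)))
      lines <- c(lines, sprintf(
        "%s\tfixture\tfive_prime_UTR\t%d\t%d\t.\t%s\t.\tParent=%s",
        contig, utr[i, 1L] + 1L, utr[i, 2L], strand, tx_id))
  }
  lines
}

# convert a transcript-space anchored edit to a forward-strand VCF record
tx_edit_to_vcf <- function(tm, contig_seq, tx_start, ref_tx, alt_tx) {
  n <- nchar(ref_tx)
  gspan <- tm$gpos[tx_start + seq_len(n)]
  if (tm$strand == "-") {
    pos <- min(gspan)
    ref <- revcomp(ref_tx); alt <- revcomp(alt_tx)
    if (nchar(ref) != nchar(alt)) {
      # indel: re-anchor on the genomic base left of the span so the first
      # REF base is shared, as VCF convention expects
      pos <- pos - 1L
      b <- substr(contig_seq, pos + 1L, pos + 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
    }
  } else {
    pos <- gspan[1L]
    ref <- ref_tx; alt <- alt_tx
  }
  stopifnot(substr(contig_seq, pos + 1L, pos + nchar(ref)) == ref)
  list(contig = tm$contig, pos = pos, ref = ref, alt = alt, filter = "PASS")
}

write_fixture_vcf <- function(rows, acc_ids, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FILTER=<ID=LowQual,Description=\"Low quality\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(acc_ids, collapse = "\t")))
  body <- vapply(rows, function(r)
    paste(c(r$contig, r$pos + 1L, r$id, r$ref, r$alt, "99", r$filter, ".",
            "GT", r$gt), collapse = "\t"), "")
  ord <- order(vapply(rows, `[[`, "", "contig"),
               vapply(rows, function(r) r$pos, 0L))
  writeLines(c(hdr, body[ord]), path)
}

# expected Level1.Level2 identifiers for the observed forms of one gene,
# following the documented composite ordering (all forms share one anchor)
expected_identifiers <- function(scen, sc, events, cds_len) {
  observed <- list()
  if (sc$ref_uorf)
    observed$reference <- list(len = scenario_ref_len(scen, cds_len),
                               rank = 0L, n_snps = 0L)
  for (ev in names(events))
    if (length(events[[ev]]$accessions) && !is.null(sc$events[[ev]]$form))
      observed[[ev]] <- sc$events[[ev]]$form
  if (!length(observed)) return(character())
  key <- vapply(observed, function(f) f$len * 10L + f$rank, 0L)
  groups <- sort(unique(key))
  ident <- vapply(names(observed), function(nm) {
    l1 <- match(key[[nm]], groups)
    peers <- names(observed)[key == key[[nm]]]
    peers <- peers[order(vapply(peers, function(p) observed[[p]]$n_snps, 0L))]
    sprintf("%d.%d", l1, match(nm, peers))
  }, "")
  ident
}

expected_assignments <- function(sc, events, ident, acc_ids) {
  default_id <- if (sc$ref_uorf) ident[["reference"]] else "absent"
  id <- stats::setNames(rep(default_id, length(acc_ids)), acc_ids)
  at <- stats::setNames(rep(sc$attr, length(acc_ids)), acc_ids)
  for (ev in names(events)) {
    accs <- events[[ev]]$accessions
    if (!length(accs)) next
    id[accs] <- if (is.null(sc$events[[ev]]$form)) "absent" else ident[[ev]]
    at[accs] <- sc$events[[ev]]$attr
  }
  list(identifier = as.list(id), attribute = as.list(at))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
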