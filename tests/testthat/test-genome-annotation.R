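# Gene-model loading, representative selection and coordinate liftover.

write_toy_gff <- function(lines, dir = tempfile("gff")) {
  dir.create(dir, showWarnings = FALSE)
  p <- file.path(dir, "toy.gff3")
  writeLines(c("##gff-version 3", lines), p)
  p
}

write_toy_fasta <- function(contigs, dir = tempfile("fa")) {
  dir.create(dir, showWarnings = FALSE)
  p <- file.path(dir, "toy.fa")
  writeLines(unlist(lapply(names(contigs), function(n)
    c(paste0(">", n), contigs[[n]]))), p)
  p
}

test_that("leader length is derived from exon/CDS geometry on both strands", {
  # 2-exon plus-strand gene: 60 nt UTR then CDS; mirrored minus-strand twin
  set.seed(1)
  utr <- strrep("C", 60)
  cds <- paste0("ATG", strrep("GGT", 5), "TGA")   # 21 nt
  exon1 <- paste0(utr, substr(cds, 1, 6))         # 66 nt
  exon2 <- substring(cds, 7)                      # 15 nt
  intron <- strrep("T", 30)
  contig_p <- paste0(strrep("G", 10), exon1, intron, exon2, strrep("G", 10))
  gffp <- c(
    "chrP\tt\tgene\t11\t121\t.\t+\t.\tID=GP",
    "chrP\tt\tmRNA\t11\t121\t.\t+\t.\tID=GP.1;Parent=GP",
    "chrP\tt\texon\t11\t76\t.\t+\t.\tParent=GP.1",
    "chrP\tt\texon\t107\t121\t.\t+\t.\tParent=GP.1",
    "chrP\tt\tCDS\t71\t76\t.\t+\t0\tParent=GP.1",
    "chrP\tt\tCDS\t107\t121\t.\t+\t0\tParent=GP.1")
  contig_m <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(contig_p)))
  L <- nchar(contig_p)
  flip <- function(a, b) c(L - b + 1L, L - a + 1L)
  mk <- function(a, b, type, attrs)
    sprintf("chrM\tt\t%s\t%d\t%d\t.\t-\t.\t%s", type,
            flip(a, b)[1], flip(a, b)[2], attrs)
  gffm <- c(mk(11, 121, "gene", "ID=GM"), mk(11, 121, "mRNA",
                                             "ID=GM.1;Parent=GM"),
            mk(11, 76, "exon", "Parent=GM.1"),
            mk(107, 121, "exon", "Parent=GM.1"),
            mk(71, 76, "CDS", "Parent=GM.1"),
            mk(107, 121, "CDS", "Parent=GM.1"))
  fa <- write_toy_fasta(list(chrP = contig_p, chrM = contig_m))
  gff <- write_toy_gff(c(gffp, gffm))
  genome <- read_genome(fa)
  ann <- load_annotation(gff, genome)
  expect_setequal(names(ann$models), c("GP.1", "GM.1"))
  expect_equal(ann$models[["GP.1"]]$leader_len, 60L)
  expect_equal(ann$models[["GM.1"]]$leader_len, 60L)
  expect_equal(ann$models[["GP.1"]]$cds_len, 21L)
  expect_equal(ann$models[["GM.1"]]$cds_len, 21L)
  # spliced cDNA identical for the mirrored gene
  sp <- spliced_cdna(ann$models[["GP.1"]], genome)
  sm <- spliced_cdna(ann$models[["GM.1"]], genome)
  expect_identical(sp$seq, sm$seq)
  expect_identical(sp$morf_start, 60L)
})

test_that("CDS length not divisible by 3 excludes the transcript with a reason", {
  contig <- paste0(strrep("C", 10), "ATG", strrep("G", 97), strrep("C", 10))
  fa <- write_toy_fasta(list(chr1 = contig))
  gff <- write_toy_gff(c(
    "chr1\tt\tgene\t1\t117\t.\t+\t.\tID=G1",
    "chr1\tt\tmRNA\t1\t117\t.\t+\t.\tID=G1.1;Parent=G1",
    "chr1\tt\texon\t1\t117\t.\t+\t.\tParent=G1.1",
    "chr1\tt\tCDS\t11\t110\t.\t+\t0\tParent=G1.1"))   # 100 nt CDS
  ann <- load_annotation(gff, read_genome(fa))
  expect_length(ann$models, 0L)
  expect_match(ann$excluded$reason, "not multiple of 3")
})

test_that("representative selection picks the smallest model suffix unless overridden", {
  mk <- function(tx) transcript_model("G", tx, "c", "+",
                                      cbind(0L, 30L), 9L, 30L)
  models <- list(`G.2` = mk("G.2"), `G.1` = mk("G.1"), `G.3` = mk("G.3"))
  sel <- select_representative(models)
  expect_equal(sel$representative[["G"]]$transcript_id, "G.1")
  only2 <- select_representative(models["G.2"])
  expect_equal(only2$representative[["G"]]$transcript_id, "G.2")
  ov <- select_representative(models,
                              override = data.frame(gene_id = "G",
                                                    transcript_id = "G.2"))
  expect_equal(ov$representative[["G"]]$transcript_id, "G.2")
  noparse <- select_representative(
    list(X = transcript_model("X", "NOSUFFIX", "c", "+",
                              cbind(0L, 30L), 9L, 30L)))
  expect_length(noparse$representative, 0L)
  expect_match(noparse$excluded_genes$reason, "suffix")
})

test_that("coordinate mapping round-trips on every exonic base of fixture transcripts", {
  fx <- fixture_universe()
  genome <- read_genome(fx$fasta)
  ann <- load_annotation(fx$gff3, genome)
  for (tm in ann$models) {
    sp <- spliced_cdna(tm, genome)
    offs <- seq_len(nchar(sp$seq)) - 1L
    gpos <- map_coordinate(sp, offs, "to_genome")
    back <- map_coordinate(sp, gpos, "to_transcript")
    expect_identical(back, offs)
    # monotone: strictly increasing on +, decreasing on -
    expect_true(all(if (tm$strand == "+") diff(gpos) > 0 else diff(gpos) < 0))
    # conservation: lengths add up
    expect_identical(nchar(sp$seq), sum(tm$exons[, 2] - tm$exons[, 1]))
    expect_identical(tm$leader_len + tm$cds_len + tm$trailer_len,
                     nchar(sp$seq))
  }
  # anchor cases: offset 0 maps to exon edge on either strand
  plus <- Filter(function(m) m$strand == "+", ann$models)[[1]]
  minus <- Filter(function(m) m$strand == "-", ann$models)[[1]]
  expect_identical(map_coordinate(spliced_cdna(plus, genome), 0L,
                                  "to_genome"),
                   min(plus$exons[, 1]))
  expect_identical(map_coordinate(spliced_cdna(minus, genome), 0L,
                                  "to_genome"),
                   max(minus$exons[, 2]) - 1L)
  # intronic position maps to NA
  multi <- Filter(function(m) nrow(m$exons) > 1, ann$models)[[1]]
  intron_pos <- multi$exons[1, 2]            # first base past exon 1
  expect_true(is.na(map_coordinate(spliced_cdna(multi, genome),
                                   intron_pos, "to_transcript")))
})

test_that("strand symmetry: mirrored genomes leave every cDNA unchanged", {
  fx <- fixture_universe()
  genome <- read_genome(fx$fasta)
  ann <- load_annotation(fx$gff3, genome)
  for (tm in ann$models[1:4]) {
    contig <- genome[[tm$contig]]
    L <- nchar(contig)
    rc_genome <- stats::setNames(
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(contig))), tm$contig)
    mirror <- transcript_model(tm$gene_id, tm$transcript_id, tm$contig,
                               if (tm$strand == "+") "-" else "+",
                               cbind(L - tm$exons[, 2], L - tm$exons[, 1]),
                               L - tm$cds_end, L - tm$cds_start)
    expect_identical(spliced_cdna(mirror, rc_genome)$seq,
                     spliced_cdna(tm, genome)$seq)
  }
})
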