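# VCF filtering, the mORF-start screen, pseudo-cDNA construction and causal
# variant attribution.

write_vcf <- function(rows, samples, dir = tempfile("vcf")) {
  dir.create(dir, showWarnings = FALSE)
  p <- file.path(dir, "t.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depth\">",
    "##FILTER=<ID=LowQual,Description=\"lq\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           paste(samples, collapse = "\t")),
    rows), p)
  p
}

test_that("FILTER, homozygosity and allele-depth policies are applied", {
  p <- write_vcf(c(
    "chr1\t5\tv1\tC\tA\t50\tPASS\t.\tGT:AD\t1/1:0,20\t0/1:10,10",
    "chr1\t7\tv2\tC\tT\t50\tLowQual\t.\tGT:AD\t1/1:0,20\t1/1:0,20",
    "chr1\t9\tv3\tG\tA\t50\t.\t.\tGT:AD\t1/1:5,15\t./.:.",
    "chr1\t11\tv4\tG\tA,T\t50\tPASS\t.\tGT:AD\t1/1:0,20,0\t2/2:0,0,20"),
    c("s1", "s2"))
  vs <- read_variants(p, af_threshold = 0.90)
  # LowQual dropped; multi-allelic split into two records
  expect_setequal(vs$variants$variant_id, c("v1", "v3", "v4_1", "v4_2"))
  expect_true(vs$genotypes["v1", "s1"])       # hom, AF 1.0
  expect_false(vs$genotypes["v1", "s2"])      # heterozygous
  expect_false(vs$genotypes["v3", "s1"])      # AF 0.75 < 0.90
  expect_false(vs$genotypes["v3", "s2"])      # missing genotype
  expect_true(vs$genotypes["v4_1", "s1"])     # allele 1 hom
  expect_false(vs$genotypes["v4_1", "s2"])
  expect_true(vs$genotypes["v4_2", "s2"])     # allele 2 hom
  # relaxing the threshold admits the AF 0.75 call
  vs2 <- read_variants(p, af_threshold = 0.5)
  expect_true(vs2$genotypes["v3", "s1"])
  # classes
  expect_true(all(vs$variants$class == "SNP"))
})

test_that("indel classes are derived from allele lengths", {
  p <- write_vcf(c(
    "chr1\t5\td1\tCAA\tC\t50\tPASS\t.\tGT\t1/1",
    "chr1\t9\ti1\tG\tGTT\t50\tPASS\t.\tGT\t1/1",
    "chr1\t12\tm1\tAC\tGT\t50\tPASS\t.\tGT\t1/1"), "s1")
  vs <- read_variants(p)
  expect_equal(vs$variants$class[match(c("d1", "i1", "m1"),
                                       vs$variants$variant_id)],
               c("deletion", "insertion", "MNP"))
})

test_that("the mORF-start screen drops genes whose start codon is hit", {
  # plain single-exon plus-strand transcript: leader 10 nt, CDS at 10..30
  contig <- paste0(strrep("C", 10), "ATG", strrep("GGT", 5), "TGACCCC")
  tm <- transcript_model("G", "G.1", "chr1", "+", cbind(0L, nchar(contig)),
                         10L, 31L)
  sp <- spliced_cdna(tm, stats::setNames(contig, "chr1"))
  mkav <- function(pos, ref, alt) {
    p <- write_vcf(sprintf("chr1\t%d\tx\t%s\t%s\t50\tPASS\t.\tGT\t1/1",
                           pos, ref, alt), "s1")
    accession_variants(read_variants(p), "s1", sp)
  }
  expect_false(screen_morf_start(sp, mkav(12, "T", "A")))  # 2nd codon base
  expect_false(screen_morf_start(sp, mkav(10, "CA", "C"))) # del covers base 1
  expect_true(screen_morf_start(sp, mkav(1, "C", "T")))    # 10 nt upstream
})

test_that("pseudo-cDNA bookkeeping: substitutions, indels, identity", {
  contig <- paste0("CCCC", "ATGAAAAAATAA", "CCCC", "ATGCTTGATTGA", "CC")
  tm <- transcript_model("G", "G.1", "chr1", "+", cbind(0L, nchar(contig)),
                         20L, 32L)
  genome <- stats::setNames(contig, "chr1")
  sp <- spliced_cdna(tm, genome)
  vcf <- write_vcf(c(
    "chr1\t5\tsnp\tA\tC\t50\tPASS\t.\tGT\t1/1\t0/0",
    "chr1\t7\tdel\tGAA\tG\t50\tPASS\t.\tGT\t0/0\t1/1"), c("s1", "s2"))
  vs <- read_variants(vcf)
  # single SNP: one base changes, length unchanged
  av1 <- accession_variants(vs, "s1", sp)
  ps1 <- build_pseudo_cdna(sp, av1, "s1")
  expect_equal(nchar(ps1$seq), nchar(sp$seq))
  expect_equal(sum(strsplit(ps1$seq, "")[[1]] !=
                     strsplit(sp$seq, "")[[1]]), 1L)
  expect_equal(ps1$morf_start, sp$morf_start)
  # 2 nt deletion in the leader shifts the mORF start by -2
  av2 <- accession_variants(vs, "s2", sp)
  ps2 <- build_pseudo_cdna(sp, av2, "s2")
  expect_equal(nchar(ps2$seq), nchar(sp$seq) - 2L)
  expect_equal(ps2$morf_start, sp$morf_start - 2L)
  # zero variants: identity
  ps0 <- build_pseudo_cdna(sp, av1[0, , drop = FALSE], "none")
  expect_identical(ps0$seq, sp$seq)
  expect_identical(ps0$gmap, sp$gmap)
  # reversibility
  expect_identical(invert_pseudo_cdna(ps1), sp$seq)
  expect_identical(invert_pseudo_cdna(ps2), sp$seq)
})

test_that("pseudo-cDNA edits are strand-aware and order-invariant", {
  fx <- fixture_universe()
  genome <- read_genome(fx$fasta)
  ann <- load_annotation(fx$gff3, genome)
  vs <- read_variants(fx$vcf)
  truth <- fx$truth
  for (gid in names(truth$genes)[1:6]) {
    tg <- truth$genes[[gid]]
    sp <- spliced_cdna(ann$models[[tg$transcript_id]], genome)
    for (acc in truth$accessions[c(1, 5, 9)]) {
      av <- accession_variants(vs, acc, sp)
      ps <- build_pseudo_cdna(sp, av, acc)
      delta <- sum(nchar(ps$applied$alt_tx) - nchar(ps$applied$ref_tx))
      expect_equal(nchar(ps$seq) - nchar(sp$seq), delta)
      expect_identical(invert_pseudo_cdna(ps), sp$seq)
      # determinism under input reordering of the variant set
      if (nrow(av) > 1) {
        ps_r <- build_pseudo_cdna(sp, av[rev(seq_len(nrow(av))), ], acc)
        expect_identical(ps_r$seq, ps$seq)
        expect_identical(ps_r$gmap, ps$gmap)
      }
    }
  }
})

test_that("causal variants are the edits intersecting the uORF interval", {
  contig <- paste0("CCCC", "ATGAAAAAATAA", "CCCC", "ATGCTTGATTGA", "CC")
  tm <- transcript_model("G", "G.1", "chr1", "+", cbind(0L, nchar(contig)),
                         20L, 32L)
  sp <- spliced_cdna(tm, stats::setNames(contig, "chr1"))
  vcf <- write_vcf(c(
    "chr1\t9\tin1\tA\tG\t50\tPASS\t.\tGT\t1/1",     # inside uORF
    "chr1\t12\tin2\tA\tG\t50\tPASS\t.\tGT\t1/1",    # inside uORF
    "chr1\t18\tout\tC\tT\t50\tPASS\t.\tGT\t1/1"),   # 3' of uORF stop
    "s1")
  av <- accession_variants(read_variants(vcf), "s1", sp)
  ps <- build_pseudo_cdna(sp, av, "s1")
  u <- find_uorfs(ps)
  expect_equal(nrow(u), 1L)
  cv <- causal_variants(ps, u$start, u$stop_end)
  expect_setequal(cv$variant_ids, c("in1", "in2"))
  expect_equal(cv$n_snps, 2L)
  expect_equal(cv$n_indels, 0L)
  # reference-identical uORF has no causal variants
  ps0 <- build_pseudo_cdna(sp, av[0, , drop = FALSE], "x")
  u0 <- find_uorfs(ps0)
  cv0 <- causal_variants(ps0, u0$start, u0$stop_end)
  expect_length(cv0$variant_ids, 0L)
})
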