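# Anchoring, Level1.Level2 identifier assignment and event classification.

mk_forms <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    d <- data.frame(anchor = r$anchor, length_nt = r$len,
                    sequence = r$seq, type = r$type %||% "Type1",
                    origin_class = r$origin,
                    n_snps = r$n_snps %||% 0L,
                    n_indels = r$n_indels %||% 0L,
                    snp_positions = r$snp_pos %||% "",
                    var_positions = r$var_pos %||% "",
                    variant_ids = r$ids %||% "",
                    insertion_origin = FALSE,
                    is_reference = isTRUE(r$ref),
                    accessions = r$acc %||% "REF",
                    stringsAsFactors = FALSE)
    d
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a single invariant reference uORF is numbered 1.1", {
  f <- assign_identifiers(mk_forms(
    list(anchor = 102L, len = 9L, seq = "ATGAAATAA",
         origin = "reference-identical", ref = TRUE)))
  expect_equal(f$identifier, "1.1")
})

test_that("SNP substitutions share Level1 with the reference and rank after it", {
  f <- assign_identifiers(mk_forms(
    list(anchor = 102L, len = 9L, seq = "ATGAAATAA",
         origin = "reference-identical", ref = TRUE),
    list(anchor = 102L, len = 9L, seq = "ATGAGATAA", origin = "SNP-only",
         n_snps = 1L, snp_pos = "106", acc = "a1")))
  expect_setequal(f$identifier, c("1.1", "1.2"))
  expect_equal(f$identifier[f$is_reference], "1.1")
})

test_that("created upstream uORFs renumber downstream reference loci", {
  f <- assign_identifiers(mk_forms(
    list(anchor = 90L, len = 9L, seq = "ATGCCCTAA", origin = "SNP-only",
         n_snps = 1L, acc = "a1"),
    list(anchor = 102L, len = 9L, seq = "ATGAAATAA",
         origin = "reference-identical", ref = TRUE)))
  expect_equal(f$identifier[f$anchor == 90L], "1.1")
  expect_equal(f$identifier[f$anchor == 102L], "2.1")
})

test_that("Level1 orders by length then deletion before insertion at one anchor", {
  f <- assign_identifiers(mk_forms(
    list(anchor = 50L, len = 12L, seq = "ATGAAAAAATAA",
         origin = "reference-identical", ref = TRUE),
    list(anchor = 50L, len = 9L, seq = "ATGAAATAA",
         origin = "deletion-bearing", n_indels = 1L, acc = "a1"),
    list(anchor = 50L, len = 15L, seq = "ATGAAAAAAAAATAA",
         origin = "insertion-bearing", n_indels = 1L, acc = "a2"),
    list(anchor = 50L, len = 9L, seq = "ATGAAGTAA",
         origin = "insertion-bearing", n_indels = 1L, n_snps = 1L,
         snp_pos = "55", acc = "a3")))
  # equal-length deletion and insertion forms get distinct Level1 groups,
  # deletion first
  expect_equal(f$identifier[f$origin_class == "deletion-bearing"], "1.1")
  expect_equal(f$identifier[f$sequence == "ATGAAGTAA"], "2.1")
  expect_equal(f$identifier[f$is_reference], "3.1")
  expect_equal(f$identifier[f$length_nt == 15L], "4.1")
})

test_that("identifier assignment matches the brute-force oracle and is gap-free", {
  fx <- fixture_universe()
  genome <- read_genome(fx$fasta)
  ann <- load_annotation(fx$gff3, genome)
  vs <- read_variants(fx$vcf)
  for (gid in names(fx$truth$genes)) {
    tg <- fx$truth$genes[[gid]]
    tm <- ann$models[[tg$transcript_id]]
    res <- analyze_gene(tm, genome, vs)
    f <- res$forms
    if (!nrow(f)) next
    expect_identical(f$identifier, oracle_identifiers(f))
    # continuity: Level1 exactly 1..n, Level2 exactly 1..m per group
    expect_identical(sort(unique(f$level1)), seq_len(max(f$level1)))
    for (g in unique(f$level1))
      expect_identical(sort(f$level2[f$level1 == g]),
                       seq_len(sum(f$level1 == g)))
  }
})

test_that("identifier assignment is invariant under accession permutation", {
  fx <- fixture_universe()
  genome <- read_genome(fx$fasta)
  ann <- load_annotation(fx$gff3, genome)
  vs <- read_variants(fx$vcf)
  tg <- fx$truth$genes[["GENE01"]]
  tm <- ann$models[[tg$transcript_id]]
  a <- analyze_gene(tm, genome, vs, accessions = fx$truth$accessions)
  b <- analyze_gene(tm, genome, vs,
                    accessions = rev(fx$truth$accessions))
  key <- function(f) f[order(f$anchor, f$sequence),
                       c("anchor", "sequence", "identifier")]
  fa <- key(a$forms); fb <- key(b$forms)
  rownames(fa) <- rownames(fb) <- NULL
  expect_identical(fa, fb)
})

test_that("anchors survive upstream deletions and flag insertion origins", {
  contig <- paste0("CCCCCC", "ATGAAATAA", "CCCC", "ATGCTTGATTGA")
  tm <- transcript_model("G", "G.1", "chr1", "+", cbind(0L, nchar(contig)),
                         19L, 31L)
  sp <- spliced_cdna(tm, stats::setNames(contig, "chr1"))
  expect_equal(anchor_uorf(sp, 6L)$anchor, 6L)
  # 2 nt deletion upstream: uORF slides to offset 4 but keeps anchor 6
  vcf_dir <- tempfile(); dir.create(vcf_dir)
  vcf <- file.path(vcf_dir, "v.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t2\tdel2\tCCC\tC\t50\tPASS\t.\tGT\t1/1",
               "chr1\t16\tins\tC\tCATGTAAC\t50\tPASS\t.\tGT\t1/1"), vcf)
  vs <- read_variants(vcf)
  ps <- build_pseudo_cdna(sp, accession_variants(vs, "s1", sp), "s1")
  u <- find_uorfs(ps)
  ref_u <- u[substring(ps$seq, u$start + 1, u$start + 9) == "ATGAAATAA", ]
  expect_equal(anchor_uorf(ps, ref_u$start)$anchor, 6L)
  expect_false(anchor_uorf(ps, ref_u$start)$insertion_origin)
  # the ATG planted wholly inside the insertion anchors to the insertion
  # point and is flagged
  new_u <- u[u$start != ref_u$start, ]
  expect_equal(nrow(new_u), 1L)
  expect_equal(new_u$length_nt, 6L)
  an <- anchor_uorf(ps, new_u$start)
  expect_true(an$insertion_origin)
  expect_equal(an$anchor, 15L)
})

test_that("events are classified per locus: creation, loss, change, switch", {
  fx <- fixture_universe()
  genome <- read_genome(fx$fasta)
  ann <- load_annotation(fx$gff3, genome)
  vs <- read_variants(fx$vcf)
  truth <- fx$truth
  for (gid in names(truth$genes)) {
    tg <- truth$genes[[gid]]
    res <- analyze_gene(ann$models[[tg$transcript_id]], genome, vs)
    ev <- res$events
    for (nm in names(tg$events)) {
      accs <- tg$events[[nm]]$accessions
      expected <- sub("length_change_(del|ins)", "length_change", nm)
      for (acc in accs)
        expect_true(any(ev$accession == acc & ev$event == expected &
                          ev$anchor == tg$locus_anchor),
                    label = paste(gid, nm, acc))
      if (nm == "type_switch")
        for (acc in accs)
          expect_true(any(ev$accession == acc & ev$event == "type_switch" &
                            ev$from_type == "Type1" & ev$to_type == "Type2"))
    }
    # unchanged accessions carry the reference identifier
    carriers <- unlist(lapply(tg$events, `[[`, "accessions"))
    calm <- setdiff(truth$accessions, carriers)
    if (isTRUE(tg$ref_uorf) && length(calm)) {
      un <- ev[ev$event == "unchanged" & ev$anchor == tg$locus_anchor, ]
      expect_setequal(un$accession, calm)
    }
  }
})
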