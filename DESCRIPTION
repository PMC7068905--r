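Package: uorfvar
Title: Discovery and Population-Level Analysis of Upstream Open Reading Frame Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds and classifies upstream open reading frames (uORFs) in
    annotated 5' leaders of spliced transcripts, applies filtered homozygous
    population variants (SNPs and INDELs) to build per-accession pseudo-cDNA
    sequences, anchors every uORF form back to reference genome coordinates,
    and assigns two-level (Level1.Level2) uORF-variant identifiers together
    with stratified population frequencies, type-transition calls and
    causal-variant summaries. Includes a deterministic synthetic-fixture
    generator (genome FASTA, GFF3, multi-sample VCF, metadata and truth
    tables) for closed-loop validation, and a single-sequence mode that takes
    a cDNA and its CDS directly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
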