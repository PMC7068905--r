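# uorfvar

Population-scale analysis of upstream open reading frame (uORF) variation.

Upstream ORFs are short coding elements in the 5′ leader of an mRNA. When a
scanning ribosome initiates at an upstream AUG it usually represses
translation of the downstream main ORF (mORF), so mutations that create,
destroy, or reshape a uORF are a recurrent source of regulatory variation.
`uorfvar` takes a reference genome, a GFF3 annotation, and a population VCF
of filtered homozygous variants, and for every annotated gene reconstructs
each accession's 5′ leader sequence, re-scans it for uORFs, and summarises
how uORF content varies across the population.

## The model

**uORF classes.** A uORF starts at a start codon (AUG by default;
near-cognate codons such as CUG/GUG can be enabled) strictly 5′ of the mORF
start and runs in-frame to the first stop codon:

* **Type1** — the stop codon lies entirely within the leader: a complete,
  independent uORF.
* **Type2** — the reading frame runs past the mORF start out of frame (or
  otherwise overlaps the mORF region without sharing its stop).
* **Type3** — the uORF is in frame with the mORF and shares its stop codon:
  an N-terminal extension.

Each uORF carries its peptide, its initiation-codon context (the 7-mer from
−3 to +4 around the A of the start codon, N-padded at sequence ends), a
Kozak-consensus flag ((A/G)CCAUGG), the 5′ space (cap to start) and the
signed 3′ space (uORF stop to mORF start).

**Pseudo-cDNA reconstruction.** For each accession, homozygous PASS variants
whose supporting-read fraction passes a threshold (default 0.90) are applied
to the spliced transcript, indels included, in descending transcript-offset
order. Every base keeps a *genomic anchor*: substituted bases keep their
reference coordinate, inserted bases anchor to the reference base
immediately 5′ of the insertion point and are flagged. Accessions with a
variant hitting the mORF start codon are dropped for that gene, since the
coordinate system would lose its fixed point.

**Identifiers.** All distinct (anchor, sequence) uORF forms of a gene are
numbered `Level1.Level2`: Level1 groups forms by (anchor, length,
origin class) with reference/SNP-only before deletion-bearing before
insertion-bearing; Level2 orders within a group by SNP count, SNP positions,
then sequence. Numbering is deterministic and gap-free from `1.1`.

**Population summaries.** Per gene the package reports per-accession events
(creation, loss, length change, substitution, type switch), stratified
occurrence frequencies (total plus latitude bins or labelled groups) that
sum to 1 per uORF locus, gene-level type transitions restricted to the three
headline classes (`Type1-only<->Type2`, `uORF-free<->Type1-only`,
`uORF-free<->Type2`) both across accessions and across splicing models, and
the fraction of variant uORF forms caused by two or more variants.

## Worked example

Classify the uORFs of a single cDNA given its CDS:

```r
library(uorfvar)
find_uorfs_single("CCATGAAATGAGGATGTTTTAG", "ATGTTTTAG")
#>   transcript_id start stop_end  type length_nt peptide     icc kozak space5
#> 1         query     2       11 Type1         9      MK NCCATGA FALSE      2
#> 2         query     7       22 Type3        15    MRMF GAAATGA FALSE      7
#>   space3 start_codon
#> 1      2         ATG
#> 2     -9         ATG
```

Run the full population pipeline on a simulated universe (the generator
writes FASTA + GFF3 + VCF + metadata plus a machine-readable truth table):

```r
dir <- tempfile("demo")
generate_fixture(fixture_config(n_genes = 4L, n_accessions = 8L, seed = 42L), dir)
res <- run_population(file.path(dir, "genome.fa"),
                      file.path(dir, "annotation.gff3"),
                      file.path(dir, "variants.vcf"),
                      file.path(dir, "metadata.tsv"))
res$forms[, c("gene_id", "identifier", "anchor", "length_nt", "type", "origin_class")]
#>    gene_id identifier anchor length_nt  type        origin_class
#> 2   GENE01        1.1     50        12 Type1 reference-identical
#> 3   GENE01        1.2     50        12 Type1            SNP-only
#> 1   GENE01        2.1     50        15 Type1   insertion-bearing
#> 11  GENE02        1.1     95        12 Type2 reference-identical
#> 12  GENE03        1.1     85        39 Type3 reference-identical
#> 13  GENE04        1.1     85         9 Type1            SNP-only

res$transitions
#>        gene_id    context  from_attr    to_attr                  class n_accessions
#> GENE01  GENE01 accessions Type1-only  uORF-free uORF-free<->Type1-only            4
#> GENE02  GENE02 accessions      Type2  uORF-free      uORF-free<->Type2            1
#> GENE04  GENE04 accessions  uORF-free Type1-only uORF-free<->Type1-only            1

res$multi_variant$fraction
#> [1] 0.3333333
```

`write_outputs(res, "outdir")` exports everything as TSV plus a JSON
manifest. The same pipeline is scriptable via
`inst/scripts/uorfvar.R` (`scan`, `find`, `population`, `simulate`
subcommands).

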