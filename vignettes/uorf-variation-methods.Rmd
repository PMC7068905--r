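---
title: "Methods: population-scale uORF variation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-scale uORF variation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfvar)
```

# Scope and model

`uorfvar` quantifies how upstream open reading frames (uORFs) vary across a
population of re-sequenced accessions. The analysis unit is one gene on one
representative transcript model; the pipeline reconstructs each accession's
spliced transcript from the reference plus its homozygous variants, re-scans
the 5′ leader, and compares what it finds against the reference scan.

## Coordinates

All internal coordinates are 0-based, half-open, on the spliced transcript
in mRNA orientation. GFF3 (1-based closed) and VCF (1-based POS) are
converted at the parsing boundary and never used internally. Anchors —
the genomic coordinates that identify a uORF locus across accessions — are
always forward-strand reference coordinates, regardless of transcript
strand.

## uORF definition and classification

A candidate uORF starts at a configured start codon (default `ATG`; add
near-cognate codons with `start_codons = c("ATG", "CTG", "GTG")`) at a
transcript offset strictly 5′ of the mORF start, and extends in frame to
the first stop codon (TAA/TAG/TGA). Classification is totalized so every
candidate receives exactly one label:

* stop entirely within the leader (`stop_end <= morf_start`) → **Type1**;
* in frame with the mORF *and* sharing its stop codon → **Type3**
  (N-terminal extension);
* any other terminated candidate → **Type2**. This bucket is dominated by
  the biologically expected case (out-of-frame overlap of the mORF start)
  but deliberately also absorbs degenerate geometries that arise in random
  or heavily mutated sequence, e.g. an in-frame candidate that stops before
  the mORF stop. Totalizing here keeps the scanner's output a partition,
  which the property-based tests rely on;
* no stop before the transcript end → `unterminated`, reported by the
  scanner but excluded from forms, identifiers and events.

Each uORF carries its peptide (Met through the residue before the stop),
the initiation-codon context (7-mer from −3 to +4 around the A of the start
codon, `N`-padded at transcript ends), a Kozak flag requiring −3 ∈ {A,G},
−2 = C, −1 = C, +4 = G, the 5′ space (cap to start) and the signed 3′
space (uORF stop to mORF start; negative when the frame runs past it).

## Gene type attribute

A gene (per splicing model, per accession) is labelled `Type2` if it has at
least one Type2 uORF, else `Type1-only` if it has at least one Type1, else
`uORF-free`. Type3-only genes are labelled `uORF-free` for transition
purposes — an N-extension does not create an independent repressive uORF —
but the scan records a separate `has_type3` flag so the information is not
lost.

## Variant filtering and pseudo-cDNA construction

`read_variants()` keeps records whose FILTER is `PASS` or `.`, splits
multi-allelic sites into one record per alternate allele, and calls an
accession a carrier only when its genotype is homozygous for that allele
and, when an `AD` field is present, the supporting-read fraction is at
least `af_threshold` (default 0.90 — homozygous calls with substantial
conflicting reads are more often mapping artefacts than real variation).

Per accession and transcript, variants are restricted to the exonic
leader + CDS region (variants 3′ of the mORF stop cannot alter uORFs);
variants straddling splice junctions or overlapping an earlier variant's
reference span are skipped with a warning. Edits are applied in descending
transcript-offset order so earlier offsets stay valid. Every base of the
resulting pseudo-cDNA keeps a genomic anchor: substituted bases keep their
reference coordinate; inserted bases anchor to the reference base
immediately 5′ (in mRNA orientation) of the insertion point and carry an
`inserted` flag. The construction is exactly invertible
(`invert_pseudo_cdna()`), which the tests use as a bookkeeping oracle.

If any variant intersects one of the three (splice-aware) genomic bases of
the mORF start codon, the gene is dropped *for that accession only*: the
mORF start is the fixed point anchoring every comparison. Dropped
accessions are excluded from the frequency denominator and tallied in the
per-gene `dropped` field, so both the conservative and the inclusive count
are recoverable.

## Forms, identifiers, events

A **form** is a distinct (anchor, sequence) pair observed on the reference
or any accession. Forms are numbered `Level1.Level2`:

* **Level1** groups forms by the triple (anchor, length, origin class),
  ordered by anchor ascending, then length ascending, then origin class:
  reference-identical and SNP-only forms (rank 0) before deletion-bearing
  (1) before insertion-bearing (2). Keying Level1 on this triple — rather
  than on anchor alone — keeps the headline distinction visible in the
  identifier: two forms share a Level1 group only when they are the same
  length *and* the same structural origin, so a length-changing indel
  always opens a new group. All anchors of a gene are sorted together, so
  a created upstream uORF renumbers downstream groups; identifiers are
  gene-internal labels, not stable cross-release accessions.
* **Level2** orders within a group by SNP count, then the comma-joined SNP
  position string (plain string comparison — documented tie-break, stable
  because positions are zero-padded free and compared identically
  everywhere), then sequence.

Numbering is continuous from `1.1` with no gaps, deterministic, and
invariant under accession input order.

Per accession and uORF locus the pipeline calls one **event**: `creation`
(absent on reference, present in accession), `loss` (the converse),
`length_change`, `substitution` (same length, different sequence),
`unchanged`; a `type_switch` row is added whenever the accession's uORF
type differs from the reference type at a shared anchor.

## Population summaries

Frequencies are occurrence fractions per uORF locus: each analyzable
accession contributes its carried form (or `absent`), so every frequency
column — total and each group column — sums to 1 per anchor. Groups come
from accession metadata: closed-left latitude bins of `lat_bin` degrees
(default 15°, `[30,45)` style labels, `unassigned` for missing values) or
arbitrary labels. Gene-level type transitions are restricted to the three
headline classes `Type1-only<->Type2`, `uORF-free<->Type1-only`,
`uORF-free<->Type2`, and are computed both across accessions (reference
attribute vs each accession's) and across splicing models of the reference
annotation. The multi-variant fraction is the share of non-reference forms
caused by ≥ 2 variants (SNPs + indels); it is `NA` when no variant form
exists.

# The synthetic fixture generator

Real inputs of this kind are genome-scale resequencing panels; the
generator produces a miniature universe with the same file formats (FASTA,
GFF3, VCF with GT/AD fields, metadata TSV) and a machine-readable truth
table (JSON), so the whole pipeline can be exercised closed-loop. Per gene
it plants one of five scenarios — a leader Type1 uORF, an mORF-overlapping
Type2, a shared-stop Type3, a uORF-free leader with a latent creation site,
and a Type1 that a single SNP switches to Type2 — across alternating
strands and 1–3 exon structures, plus a second splicing model that splices
the uORF out. Accessions draw mutually exclusive events (loss,
substitution, length-changing deletion/insertion, creation, type switch)
at `event_rate` (default 0.15, low enough that most accessions stay
reference-like, as in real panels), and distractor records (heterozygous
and FILTER-failing) are planted at `distractor_rate` to exercise the
filters. All randomness is integer-based (`sample.int`) so fixtures are
byte-identical across platforms for a given seed. Default problem size is
10 genes × 20 accessions; the test suite also runs 10 × 200 for
bookkeeping properties.

The defaults are the study conditions: the acceptance script
(`scripts/acceptance.R`) runs exactly this configuration and reports
headline quantities plus truth-recovery rates.

# Parameter summary

| Parameter | Default | Rationale |
|---|---|---|
| `start_codons` | `"ATG"` | canonical initiation; near-cognates opt-in |
| `af_threshold` | 0.90 | reject dubious homozygous calls with conflicting reads |
| `lat_bin` | 15° | coarse climatic stratification without emptying bins |
| `event_rate` | 0.15 | sparse events, mostly reference-like accessions |
| `representative_only` | `TRUE` | one model per gene for population statistics |

# Worked call

```{r example}
u <- find_uorfs_single("CCATGAAATGAGGATGTTTTAG", "ATGTTTTAG")
u[, c("start", "stop_end", "type", "length_nt", "peptide", "icc")]
```
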