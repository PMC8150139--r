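---
title: "Annotating uORF-perturbing 5'UTR variants: methods and design"
author: "uORFannotate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating uORF-perturbing 5'UTR variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uORFannotate)
```

## The biology and the problem

Upstream open reading frames (uORFs) are short coding units within 5'
untranslated regions. A scanning ribosome that initiates at an upstream AUG
(uAUG) translates the uORF and, depending on where the uORF ends, may fail
to reinitiate at the main start codon; uORFs therefore repress downstream
protein output. Small variants that create or destroy uORF starts and
stops can cause disease through altered protein dosage, yet generic
variant annotators label them only as "5' UTR variant".

`uORFannotate` classifies, for every transcript whose spliced 5'UTR
contains a given small variant (SNV, MNV, or indel of at most 5 bp), five
consequence classes:

* **uAUG_gained** — the alternate allele creates a new AUG upstream of the
  CDS;
* **uAUG_lost** — a reference uAUG no longer reads AUG;
* **uSTOP_lost** — the stop codon of an existing uORF is destroyed;
* **uSTOP_gained** — an existing (u)ORF acquires an earlier in-frame stop;
* **uFrameshift** — an indel whose net length change is not a multiple of
  three shifts the frame of an existing (u)ORF.

One variant can have several consequences (on one or several uORFs, and on
one or several transcripts); each is reported as its own row.

## ORF model

Within a spliced 5'UTR of length $L$ (offset 0 = cap-proximal base), an
ORF starts at each AUG and is walked codon by codon. If a stop codon (TAA,
TAG, TGA) occurs wholly inside the UTR, the ORF is a distinct **uORF**.
Otherwise the ORF overlaps the CDS: when $(L - s) \bmod 3 = 0$ for start
offset $s$ it is an in-frame N-terminal extension (**inframe_oORF**), else
an **OutOfFrame_oORF**. A codon straddling the UTR/CDS junction counts as
not-in-UTR. Each AUG defines its own ORF even when several share a stop,
because each start site is independently perturbable; the reference census
(`existing_uORFs`, `existing_InFrame_oORFs`, `existing_OutOfFrame_oORFs`)
therefore sums to the number of UTR AUGs.

Only canonical AUG starts are considered. Near-cognate starts (CUG, GUG,
...) are known to initiate many translated uORFs but their variant-level
interpretation is unsettled; they are out of scope.

## Kozak strength

Initiation efficiency depends on the context around the AUG. The package
reports the 7-mer covering positions $-3..+4$ (the AUG is characters 4-6)
and a three-level strength based on the two classical determinants:

* **Strong** — purine (A/G) at $-3$ *and* G at $+4$;
* **Moderate** — exactly one of the two;
* **Weak** — neither.

Positions upstream of the cap pad with `N` (which fails both tests); the
$+4$ base of a junction-proximal AUG is read from the CDS. The three-level
rule rather than a position-weight matrix is a deliberate design choice:
it is the conventional clinical-genetics reading of the Kozak consensus
and keeps the output categorical.

## Variant handling

VCF alleles are normalized by trimming the shared prefix (advancing `pos`)
and then the shared suffix, yielding minimal alleles of which one may be
empty. Multi-allelic records are decomposed per alternate allele first.
Variants are annotated only when their reference bases (for insertions,
both flanking bases) lie wholly within the 5'UTR's exonic sequence of a
transcript and map to contiguous transcript offsets; variants touching
intron, CDS or a splice junction are skipped with a notice, as are
variants whose substitution length or net length change exceeds 5 bp
(configurable). Distances for length-changing variants are measured on the
allele where the feature exists: alternate-allele coordinates for gained
features and frameshifted starts, reference coordinates for lost features.

### Edge rules for indels

The literature does not specify how "the variant creates/destroys this
feature" behaves under indels, so the package fixes the following rules
once (the brute-force oracle encodes them independently):

* An alternate AUG is **gained** iff its 3-base window intersects the
  edited window (for pure deletions: straddles the deletion junction) and,
  for length-preserving variants, the same-offset reference window is not
  AUG. AUGs merely shifted by an upstream indel are not gained.
* A reference AUG is **lost** iff its window intersects the edit (for pure
  insertions: the insertion point falls strictly inside the AUG) and, for
  length-preserving variants, the same-offset alternate window is not AUG.
  A row about a destroyed start supersedes stop/frameshift rows for that
  same uORF; all other detectors require the start intact.
* **uSTOP_lost** requires the uORF's stop-codon window to intersect the
  edit and the codon to no longer read as a stop (any indel editing stop
  bases destroys it). The alternative-stop search walks the alternate UTR
  in the frame of the (unchanged) start and accepts the first in-frame
  stop wholly inside the alternate UTR downstream of the old stop
  position; when none exists, the frame of the resulting oORF relative to
  the CDS is reported instead.
* **uSTOP_gained** requires the first in-frame stop of the alternate walk
  to lie wholly inside the alternate UTR, to overlap the edit, and (for
  uORFs) to precede the old stop's shifted position — so an in-frame
  deletion that merely moves the same stop codon closer is not a gain.
* **uFrameshift** requires a net length change indivisible by three and
  the edit inside the ORF body (start through the stop codon's last base,
  or through the UTR end for oORFs). The subtype is reported for both
  alleles: `Type` from the reference walk, `AltType` from re-walking the
  alternate UTR from the same start.

A single variant satisfying several rules produces several rows — e.g. an
SNV destroying a uORF stop while creating an out-of-frame AUG two bases
upstream yields a `uSTOP_lost` row and a `uAUG_gained` row (fixture F2's
variant V3 is exactly this case).

## Translation evidence

Ribosome profiling catalogues (e.g. exports from small-ORF repositories)
can be supplied as a TSV keyed by (chrom, 1-based genomic position of the
uAUG first base, strand). Genomic keying lets one evidence row support the
same uAUG across overlapping transcripts. Because profiling data are
incomplete across tissues, evidence is reported as an annotation on
disrupting rows, never used as a filter at annotation time; a newly gained
uAUG cannot have pre-existing evidence, so `Evidence` is `NA` on
uAUG_gained rows.

## High-impact prioritization

`prioritizeHighImpact()` keeps rows whose variant forms a new overlapping
ORF with a Strong or Moderate Kozak start — uAUG_gained with an oORF
subtype, uSTOP_lost with no alternative stop, uFrameshift with an oORF
alternate subtype — or that disrupt a uORF with documented evidence of
translation. An optional gene list restricts rows to genes where uORF
perturbation is a plausible disease mechanism. Two interpretation choices
are deliberate: the evidence arm applies evidence alone (no additional
Kozak gate), and gene matching uses `gene_id` (supply identifiers of the
same namespace as the GTF).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `maxIndelLen` | 5 bp | scope cap on substitution length and net length change; longer indels have increasingly ambiguous annotations |
| `cdsScanHorizon` | 999 nt | how far past the start codon the oORF stop scan reads; scanning past it reports "no stop within horizon" (`StartDistanceToStop = NA`) |
| `outputFormat` | `tsv` | `tsv`, or `vcf` with annotations under the `UTRA` INFO key (pipe-delimited fields in TSV column order, entries comma-separated) |

The horizon bound keeps the per-variant work constant, which is what makes
the whole run linear in the number of input variants.

## Coordinates

GTF and VCF are 1-based inclusive on input and output; every internal
quantity (UTR offsets, the per-base genomic map, all reported distances)
is 0-based, with conversion only at the I/O boundary. Exon and CDS
intervals are held as `GRanges` (1-based, the Bioconductor convention)
inside `TranscriptModel`. The CDS start is taken from the `start_codon`
feature when present, else the 5'-most CDS base in transcript orientation,
accommodating both common GTF dialects. Soft-masked bases are uppercased;
`N` propagates and can never form an AUG or stop.

## What the fixture generator emulates — and what it does not

`makeStaticFixtures()` returns two hand-verified loci (an AUG-free UTR and
a single-uORF UTR with one variant per consequence class) in plus/minus
strand and one/two-exon layouts, with frozen expected rows.
`makeRandomFixture(seed, ...)` generates transcripts with 10-300 nt UTRs
at ~50% GC, 1-3 exons (introns 20-80 nt), random strand and CDSs of 10-40
codons, then places 1-5 bp variants class-balanced by rejection sampling,
because uniform placement under-samples stop-codon edits. Expected rows
come from an independent brute-force oracle (`oracleAnnotateEdit()`) that
re-derives ORF structure by exhaustive character scanning and shares no
code with the engine.

The generator emulates coordinate arithmetic, splicing, strandedness and
allele normalization faithfully; it does **not** emulate real human UTR
base composition (GC-rich, structured), overlapping transcripts of one
gene, chromosome-scale coordinates, or population allele distributions. A
green oracle-equivalence test therefore establishes the correctness of
the annotation logic, not calibration against any clinical dataset.

## Numerical and degenerate-input choices

* Transcripts with zero-length 5'UTRs, no locatable CDS start, or a
  chromosome absent from the FASTA are skipped with a warning.
* Alleles identical after normalization and symbolic alleles are rejected
  per record, never fatally.
* Output rows sort by (VCF record, transcript, fixed consequence order
  gained / lost / stop_lost / stop_gained / frameshift, start offset), so
  reruns are byte-identical.
* The consequence vocabulary is fixed to `uAUG_gained`, `uAUG_lost`,
  `uSTOP_lost`, `uSTOP_gained`, `uFrameshift` (one casing, chosen once).

## Known limitations

Only canonical AUG uORFs; variants longer than 5 bp are out of scope by
design; 3'UTR and other regulatory variant classes are not handled; no
pathogenicity scoring or conservation integration — the output is meant
to feed such downstream interpretation, not replace it.

## A worked example

```{r example}
bundle <- makeStaticFixtures()[["F2_plus_1exon"]]
dir <- tempfile(); dir.create(dir)
paths <- writeFixtureBundle(bundle, dir)
res <- annotateVcf(paths["vcf"], paths["gtf"], paths["fasta"],
                   outputPath = file.path(dir, "out.tsv"), verbose = FALSE)
res$annotations[, c("pos", "ref", "alt", "consequence", "KozakContext",
                    "KozakStrength", "Type", "AltType")]
```
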