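# uORFannotate

Transcript-aware annotation of 5′UTR variants that create or disrupt
upstream open reading frames (uORFs).

## Why

uORFs are short reading frames in 5′ untranslated regions that repress
translation of the downstream coding sequence. Small variants that
perturb them — creating an upstream AUG, destroying a uORF start or stop,
shortening a uORF with a premature stop, or shifting its frame — can
change protein dosage and cause disease, but standard annotators report
them only as generic "5′ UTR" variants. `uORFannotate` gives clinical and
research geneticists the missing detail for SNVs, MNVs and 1–5 bp indels.

## What it computes

For every transcript whose spliced 5′UTR (length *L*, offset 0 at the
cap) contains a variant, the package reports one row per
(variant × transcript × consequence × uORF) in five classes —
`uAUG_gained`, `uAUG_lost`, `uSTOP_lost`, `uSTOP_gained`, `uFrameshift` —
with:

- the reference uORF census: counts of distinct uORFs (stop within the
  UTR) and of overlapping ORFs, in-frame (*(L − s)* mod 3 = 0 for start
  offset *s*; an N-terminal extension) or out-of-frame;
- the Kozak 7-mer context (positions −3..+4 of the AUG) and its strength:
  **Strong** (purine at −3 *and* G at +4), **Moderate** (one of the two),
  **Weak** (neither);
- distances in nt: cap→start, start→CDS, start→stop, new-stop→CDS,
  alternative-stop→CDS, measured on the allele where the feature exists;
- uORF subtype on both alleles for frameshifts; frame with the CDS for
  stop-loss without an alternative stop;
- translation evidence from a user-supplied ribosome-profiling TSV
  (genomic position keyed), reported as an annotation, never a filter.

`prioritizeHighImpact()` implements the follow-up filter: keep rows that
form new overlapping ORFs with Strong/Moderate starts, or that disrupt
uORFs with documented translation evidence, optionally restricted to a
gene list.

## Worked example

```r
library(uORFannotate)
bundle <- makeStaticFixtures()[["F2_plus_1exon"]]   # 1 uORF, 4 variants
paths  <- writeFixtureBundle(bundle, tempdir())
res <- annotateVcf(paths["vcf"], paths["gtf"], paths["fasta"],
                   outputPath = file.path(tempdir(), "out.tsv"))
#> loaded 1 transcript model(s) from F2_plus_1exon.gtf
#> variants read 4 | annotated 4 | no 5'UTR consequence 0 | skipped: symbolic 0, ref mismatch 0, over scope 0, junction 0
#> wrote .../out.tsv
res$annotations[, c("pos","ref","alt","consequence","KozakContext",
                    "KozakStrength","Type","AltType")]
#>   pos ref alt  consequence KozakContext KozakStrength Type         AltType
#> 1   5   T   C    uAUG_lost      GCCATGA      Moderate uORF            <NA>
#> 2   7   A   T uSTOP_gained      GCCATGA      Moderate uORF            <NA>
#> 3   8   A      uFrameshift      GCCATGA      Moderate uORF OutOfFrame_oORF
#> 4  11   A   G  uAUG_gained      GAAATGG        Strong OutOfFrame_oORF <NA>
#> 5  11   A   G   uSTOP_lost      GCCATGA      Moderate <NA>            <NA>
```

Reading the rows: the T>C at position 5 destroys the uORF's AUG (Moderate
Kozak context `GCCATGA`); the A>T at 7 writes an in-frame TAA that
shortens the uORF; the 1 bp deletion at 8 (shown with its normalized
alleles) shifts the uORF out of frame so it now runs into the CDS; and
the single A>G at 11 has **two** consequences — it destroys the uORF's
TAG stop (no alternative stop exists, leaving an in-frame overlapping
ORF) *and* creates a new out-of-frame AUG in a Strong context
(`GAAATGG`). That last pair is exactly the kind of variant the
high-impact filter retains.

A command-line wrapper is installed at
`<library>/uORFannotate/exec/uorf-annotate`:

```sh
uorf-annotate --vcf in.vcf --gtf tx.gtf --fasta genome.fa \
    --out out.tsv [--format vcf] [--evidence uorfs.tsv] \
    [--gene-list genes.txt] [--high-impact-only]
```

With `--format vcf`, input records are preserved and annotated records
gain a `UTRA` INFO key (comma-separated entries, pipe-delimited fields in
TSV column order); `readAnnotatedVcf()` parses it back losslessly.

## Validation

The consequence engine is validated against an independent brute-force
oracle (`oracleAnnotateEdit()`) that re-derives ORF structure by
exhaustive character-level scanning: on thousands of seeded random
(UTR, variant) pairs and on random FASTA+GTF+VCF bundles spanning both
strands and multi-exon UTRs, engine and oracle must agree exactly. Eight
hand-verified static fixtures pin down every annotation field
byte-for-byte.

`scripts/acceptance.R` re-runs this validation end to end against the
*installed* package — all static bundles, plus a seeded random bundle
checked against the oracle — and writes its (empty) machine-readable
target object:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Canonical AUG starts only; variants ≤ 5 bp (configurable); 5′UTR
consequences only (no 3′UTR classes, no pathogenicity scores). See the
methods vignette (`vignettes/uORFannotate-methods.Rmd`) for the full rule
set, including the indel edge rules and design rationale.
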