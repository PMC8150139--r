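Package: uORFannotate
Title: Annotation of 5'UTR Variants That Create or Disrupt Upstream Open
    Reading Frames
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Transcript-aware annotation of small variants (SNVs, 1-5 bp
    indels and MNVs) in 5' untranslated regions that perturb upstream open
    reading frames (uORFs). For each variant the package detects five
    consequence classes (uAUG_gained, uAUG_lost, uSTOP_lost, uSTOP_gained,
    uFrameshift), scores start-site Kozak context strength, classifies
    uORF/oORF subtypes, computes cap/CDS/stop distances, flags ribosome
    profiling evidence of translation, and prioritizes high-impact variants
    that form overlapping ORFs with Strong or Moderate Kozak start sites.
    Includes a seeded generator of self-consistent FASTA+GTF+VCF fixtures
    with an independent brute-force oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
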