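#' @import methods
#' @importFrom S4Vectors isSingleString
NULL

#' TranscriptModel: one transcript's exon structure and CDS start
#'
#' Holds the exon and CDS intervals of a single protein-coding transcript
#' together with the genomic position of the first base of its annotated
#' start codon. Exons are stored as a \link[GenomicRanges]{GRanges} in
#' transcript (5'->3') order; the CDS start is kept 1-based genomic, as in
#' the source GTF.
#'
#' @slot transcriptId character(1) transcript identifier.
#' @slot geneId character(1) gene identifier.
#' @slot geneSymbol character(1) gene symbol; may be \code{""}.
#' @slot chrom character(1) chromosome name.
#' @slot strand character(1), \code{"+"} or \code{"-"}.
#' @slot exons \code{GRanges} of exons in transcript order.
#' @slot cdsStart integer(1), 1-based genomic position of the first base of
#'   the start codon (the 5'-most CDS base in transcript orientation).
#' @slot cdsIntervals \code{GRanges} of CDS intervals in transcript order.
#'
#' @exportClass TranscriptModel
setClass("TranscriptModel",
    representation(
        transcriptId = "character",
        geneId = "character",
        geneSymbol = "character",
        chrom = "character",
        strand = "character",
        exons = "GRanges",
        cdsStart = "integer",
        cdsIntervals = "GRanges"
    )
)

setValidity("TranscriptModel", function(object) {
    msg <- NULL
    if (!object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) == 0L)
        msg <- c(msg, "transcript must have at least one exon")
    st <- GenomicRanges::start(ex); en <- GenomicRanges::end(ex)
    if (length(ex) > 1L) {
        ok <- if (object@strand == "+") all(diff(st) > 0) && all(en[-length(en)] < st[-1L])
              else all(diff(st) < 0) && all(st[-length(st)] > en[-1L])
        if (!ok) msg <- c(msg, "exons must be non-overlapping and in transcript order")
    }
    if (length(object@cdsStart) != 1L ||
        !any(object@cdsStart >= st & object@cdsStart <= en))
        msg <- c(msg, "cdsStart must fall within an exon")
    if (is.null(msg)) TRUE else msg
})

#' SplicedUTR: the spliced 5'UTR of one transcript
#'
#' The cap-to-CDS sequence of a transcript in transcript orientation
#' (offset 0 is the cap-proximal base), together with the first bases of the
#' spliced CDS (the stop-scan horizon for overlapping ORFs) and a map from
#' each UTR offset to its 0-based genomic position.
#'
#' @slot transcriptId character(1).
#' @slot chrom character(1).
#' @slot strand character(1), \code{"+"} or \code{"-"}.
#' @slot sequence character(1), uppercase spliced 5'UTR (A/C/G/T/N only).
#' @slot cdsContext character(1), first K nt of the spliced CDS in
#'   transcript orientation (K defaults to 999, truncated at transcript end).
#' @slot genomicPositions integer vector, 0-based genomic position of each
#'   UTR offset; strictly increasing within exons on \code{+}, strictly
#'   decreasing on \code{-}.
#'
#' @exportClass SplicedUTR
setClass("SplicedUTR",
    representation(
        transcriptId = "character",
        chrom = "character",
        strand = "character",
        sequence = "character",
        cdsContext = "character",
        genomicPositions = "integer"
    )
)

setValidity("SplicedUTR", function(object) {
    msg <- NULL
    if (nchar(object@sequence) != length(object@genomicPositions))
        msg <- c(msg, "genomicPositions must have one entry per UTR base")
    if (grepl("[^ACGTN]", object@sequence))
        msg <- c(msg, "sequence may contain only A/C/G/T/N")
    if (nchar(object@sequence) < 1L)
        msg <- c(msg, "5'UTR must be non-empty")
    if (is.null(msg)) TRUE else msg
})

#' VariantRecord: one normalized VCF allele pair
#'
#' A single chrom/pos/ref/alt allele pair after shared prefix and suffix
#' trimming (prefix first). \code{pos} stays 1-based as in VCF; one of
#' \code{ref}/\code{alt} may be empty after trimming (pure indel).
#'
#' @slot chrom character(1).
#' @slot pos integer(1), 1-based position of the first trimmed ref base (for
#'   pure insertions, the base before which the insertion occurs is
#'   \code{pos - 1}).
#' @slot ref character(1) reference allele (possibly \code{""}).
#' @slot alt character(1) alternate allele (possibly \code{""}).
#' @slot variantId character(1), \code{chrom-pos-ref-alt} of the input alleles.
#'
#' @exportClass VariantRecord
setClass("VariantRecord",
    representation(
        chrom = "character",
        pos = "integer",
        ref = "character",
        alt = "character",
        variantId = "character"
    )
)

setValidity("VariantRecord", function(object) {
    msg <- NULL
    if (object@ref == object@alt)
        msg <- c(msg, "ref and alt must differ after normalization")
    if (grepl("[^ACGTN]", object@ref) || grepl("[^ACGTN]", object@alt))
        msg <- c(msg, "alleles must be plain A/C/G/T/N strings")
    if (is.null(msg)) TRUE else msg
})

#' EvidenceStore: translated-uORF evidence lookup
#'
#' A set of (chrom, 1-based genomic position of the uAUG first base, strand)
#' keys marking uORFs with ribosome-profiling (or user-supplied) evidence of
#' translation.
#'
#' @slot keys character vector of unique \code{"chrom:pos:strand"} keys.
#' @slot sourceLabel character(1) free-text provenance label.
#'
#' @exportClass EvidenceStore
setClass("EvidenceStore",
    representation(keys = "character", sourceLabel = "character")
)

setValidity("EvidenceStore", function(object) {
    if (anyDuplicated(object@keys)) "keys must be unique" else TRUE
})

#' FixtureBundle: a self-consistent mini genome + annotation + variants
#'
#' Text of a miniature FASTA, Ensembl-dialect GTF and VCFv4.2 that are
#' mutually consistent, plus the expected annotation rows ("truth") for the
#' bundled variants. Truth rows for random bundles are computed by the
#' independent brute-force oracle, not by the annotation engine.
#'
#' @slot name character(1) bundle label.
#' @slot fastaText,gtfText,vcfText character(1) file contents.
#' @slot truthRows data.frame of expected annotation rows.
#' @slot seed integer(1); 0 for hand-built static bundles.
#'
#' @exportClass FixtureBundle
setClass("FixtureBundle",
    representation(
        name = "character",
        fastaText = "character",
        gtfText = "character",
        vcfText = "character",
        truthRows = "data.frame",
        seed = "integer"
    )
)

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel", object@transcriptId,
        sprintf("(%s, %s strand)", object@chrom, object@strand), "\n")
    cat("  gene:", object@geneId,
        if (nzchar(object@geneSymbol)) sprintf("(%s)", object@geneSymbol) else "",
        "\n")
    cat("  exons:", length(object@exons),
        " cdsStart:", object@cdsStart, "\n")
})

setMethod("show", "SplicedUTR", function(object) {
    n <- nchar(object@sequence)
    cat("SplicedUTR of", object@transcriptId,
        sprintf("(%s, %s strand): %d nt\n", object@chrom, object@strand, n))
    cat("  ", if (n <= 60) object@sequence
        else paste0(substr(object@sequence, 1, 57), "..."), "\n")
})

setMethod("show", "VariantRecord", function(object) {
    cat(sprintf("VariantRecord %s:%d %s>%s [%s]\n", object@chrom, object@pos,
        ifelse(nzchar(object@ref), object@ref, "-"),
        ifelse(nzchar(object@alt), object@alt, "-"),
        variantClass(object)))
})

setMethod("show", "EvidenceStore", function(object) {
    cat("EvidenceStore:", length(object@keys), "translated uORF sites",
        if (nzchar(object@sourceLabel)) sprintf("(%s)", object@sourceLabel)
        else "", "\n")
})

setMethod("show", "FixtureBundle", function(object) {
    cat("FixtureBundle", object@name, sprintf("(seed %d):", object@seed),
        nrow(object@truthRows), "truth rows\n")
})
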