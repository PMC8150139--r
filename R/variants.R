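#' Normalize a raw VCF allele pair
#'
#' Trims the shared prefix (advancing \code{pos}) and then the shared suffix
#' of the ref/alt alleles, yielding a minimal representation in which the
#' two alleles share no common prefix or suffix. One of the trimmed alleles
#' may be empty (pure insertion or deletion).
#'
#' Symbolic alleles (\code{<DEL>}, breakends, \code{*}) cannot be
#' normalized and raise an error; callers skip such records with a notice.
#'
#' @param chrom chromosome name.
#' @param pos 1-based VCF position.
#' @param ref,alt allele strings as in the VCF.
#' @return a \linkS4class{VariantRecord} with trimmed alleles; its
#'   \code{variantId} keeps the input representation.
#' @examples
#' normalizeVariant("chr1", 5, "TCG", "TAG")  # pos 6, C>A
#' @export
normalizeVariant <- function(chrom, pos, ref, alt) {
    ref <- toupper(ref); alt <- toupper(alt)
    if (grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt))
        stop("symbolic or non-ACGTN allele: ", ref, ">", alt)
    if (ref == alt)
        stop("ref and alt are identical: ", ref)
    variantId <- paste(chrom, pos, ref, alt, sep = "-")
    pos <- as.integer(pos)
    ## shared prefix first
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
        ref <- substr(ref, 2L, nchar(ref))
        alt <- substr(alt, 2L, nchar(alt))
        pos <- pos + 1L
    }
    ## then shared suffix
    while (nchar(ref) > 0L && nchar(alt) > 0L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    new("VariantRecord", chrom = chrom, pos = pos, ref = ref, alt = alt,
        variantId = variantId)
}

#' Does a normalized variant respect the small-variant scope?
#'
#' The annotator is restricted to SNVs, MNVs and indels whose net length
#' change and substitution length are both at most \code{maxLen} (default
#' 5 bp); longer variants are outside the tool's stated scope.
#'
#' @param v a \linkS4class{VariantRecord}.
#' @param maxLen scope cap in bp.
#' @return logical(1).
#' @export
withinScope <- function(v, maxLen = 5L) {
    nr <- nchar(v@ref); na <- nchar(v@alt)
    abs(nr - na) <= maxLen && max(nr, na) <= maxLen
}

#' Apply a normalized variant to a spliced 5'UTR
#'
#' Maps the variant's genomic footprint through the UTR's coordinate map and
#' edits the spliced sequence in transcript orientation (alleles are reverse
#' complemented for minus-strand transcripts). The reference allele must lie
#' wholly within the UTR's exonic positions and map to a contiguous run of
#' transcript offsets; variants that touch intronic, CDS or flanking bases
#' — including indels spanning a splice junction — are rejected.
#'
#' For pure insertions both genomic flanking bases must map to adjacent UTR
#' offsets, so insertions at the cap or at the UTR/CDS junction (whose
#' placement is ambiguous) are rejected as well.
#'
#' @param utr a \linkS4class{SplicedUTR}.
#' @param v a \linkS4class{VariantRecord} (normalized).
#' @return list with \code{altSeq} (the alternate spliced UTR string),
#'   \code{editStart} (0-based UTR offset of the first edited base, or of
#'   the insertion point), \code{refLen}/\code{altLen} (edit lengths in UTR
#'   space), \code{utrRef}/\code{utrAlt} (alleles in transcript
#'   orientation), or \code{NULL} with a condition message via
#'   \code{reason} attribute when the variant is not applicable.
#' @export
applyVariant <- function(utr, v) {
    minus <- utr@strand == "-"
    nref <- nchar(v@ref)
    fail <- function(why) structure(list(NULL), class = "uorfNotApplicable",
                                    reason = why)
    if (v@chrom != utr@chrom) return(fail("different chromosome"))
    if (nref > 0L) {
        gpos <- (v@pos - 1L) + seq_len(nref) - 1L     # 0-based ref footprint
        off <- genomicToUtrOffset(utr, gpos)
        if (anyNA(off))
            return(fail("reference allele not wholly within 5'UTR exons"))
        o <- sort(off)
        if (nref > 1L && !all(diff(o) == 1L))
            return(fail("variant spans a splice junction"))
        e0 <- o[1L]
        utrRef <- if (minus) .revcomp(v@ref) else v@ref
        if (.sub0(utr@sequence, e0, nref) != utrRef)
            return(fail("reference allele mismatch against UTR sequence"))
    } else {
        ## pure insertion between genomic pos-2 and pos-1 (0-based)
        offL <- genomicToUtrOffset(utr, v@pos - 2L)
        offR <- genomicToUtrOffset(utr, v@pos - 1L)
        if (is.na(offL) || is.na(offR))
            return(fail("insertion point not inside the 5'UTR"))
        if (abs(offL - offR) != 1L)
            return(fail("insertion at a splice junction"))
        e0 <- max(offL, offR)
        utrRef <- ""
    }
    utrAlt <- if (minus) .revcomp(v@alt) else v@alt
    len <- utrLength(utr)
    altSeq <- paste0(substr(utr@sequence, 1L, e0), utrAlt,
                     substr(utr@sequence, e0 + nref + 1L, len))
    list(altSeq = altSeq, editStart = e0,
         refLen = nref, altLen = nchar(utrAlt),
         utrRef = utrRef, utrAlt = utrAlt)
}
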