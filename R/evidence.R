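#' Load a translated-uORF evidence list
#'
#' Reads a tab-separated file of uORFs with experimental (ribosome
#' profiling) evidence of translation. The file must carry a header with at
#' least the columns \code{chrom}, \code{start_pos} (1-based genomic
#' position of the uAUG first base) and \code{strand}; extra columns are
#' ignored. Malformed rows are skipped with a warning, and duplicate keys
#' are collapsed with a message reporting the count.
#'
#' Keys are genomic (chrom, position, strand) rather than transcript-based,
#' so one evidence row supports the same uAUG across all overlapping
#' transcripts.
#'
#' @param tsvPath path to the TSV file.
#' @param sourceLabel free-text provenance label stored with the set.
#' @param verbose emit messages.
#' @return an \linkS4class{EvidenceStore}.
#' @export
loadEvidence <- function(tsvPath, sourceLabel = basename(tsvPath),
                         verbose = TRUE) {
    if (!file.exists(tsvPath))
        stop("evidence file not found: ", tsvPath)
    tab <- utils::read.delim(tsvPath, header = TRUE, sep = "\t",
                             colClasses = "character",
                             check.names = FALSE)
    need <- c("chrom", "start_pos", "strand")
    if (!all(need %in% names(tab)))
        stop("evidence TSV must have header columns chrom, start_pos, strand")
    pos <- suppressWarnings(as.integer(tab$start_pos))
    ok <- !is.na(pos) & pos >= 1L & tab$strand %in% c("+", "-") &
        nzchar(tab$chrom)
    if (any(!ok))
        warning(sum(!ok), " malformed evidence row(s) skipped")
    keys <- paste(tab$chrom[ok], pos[ok], tab$strand[ok], sep = ":")
    ndup <- sum(duplicated(keys))
    if (ndup > 0L)
        .msg(verbose, ndup, " duplicate evidence entr(ies) collapsed")
    new("EvidenceStore", keys = unique(keys), sourceLabel = sourceLabel)
}

#' An empty evidence store
#'
#' @param sourceLabel provenance label.
#' @return an \linkS4class{EvidenceStore} with no entries.
#' @export
emptyEvidenceStore <- function(sourceLabel = "empty") {
    new("EvidenceStore", keys = character(0), sourceLabel = sourceLabel)
}

#' Query translation evidence by genomic site
#'
#' @param store an \linkS4class{EvidenceStore}.
#' @param chrom chromosome name.
#' @param pos 1-based genomic position of the uAUG first base.
#' @param strand \code{"+"} or \code{"-"}.
#' @return logical(1).
#' @export
hasEvidenceAt <- function(store, chrom, pos, strand) {
    paste(chrom, pos, strand, sep = ":") %in% store@keys
}

#' Query translation evidence for a uORF of a transcript
#'
#' Resolves the uORF's UTR start offset to its genomic position through the
#' transcript's coordinate map and looks it up in the store.
#'
#' @param store an \linkS4class{EvidenceStore}.
#' @param utr the transcript's \linkS4class{SplicedUTR}.
#' @param startOffset 0-based UTR offset of the uORF's AUG.
#' @return logical(1).
#' @export
hasEvidence <- function(store, utr, startOffset) {
    hasEvidenceAt(store, utr@chrom,
                  utr@genomicPositions[startOffset + 1L] + 1L, utr@strand)
}
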