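#' Load transcript models from a GTF and genome FASTA
#'
#' Parses an Ensembl-dialect GTF (exon, CDS and optional start_codon
#' features with \code{transcript_id}/\code{gene_id} attributes) into one
#' \linkS4class{TranscriptModel} per protein-coding transcript that has a
#' non-empty 5'UTR. The CDS start is taken from the \code{start_codon}
#' feature when present, otherwise from the 5'-most CDS base in transcript
#' orientation, so both GTF dialects are accepted.
#'
#' Transcripts are skipped, with a warning, when their chromosome is absent
#' from the FASTA, when no CDS start can be located, or when the 5'UTR has
#' length zero.
#'
#' @param gtfPath path to a GTF file.
#' @param genome a genome: FASTA path, \link[Biostrings]{DNAStringSet} or
#'   \link[Rsamtools]{FaFile}. A \code{.fai} sidecar next to a FASTA path is
#'   used when present; otherwise the FASTA is fully loaded.
#' @param verbose emit progress messages.
#' @return named list of \linkS4class{TranscriptModel} objects.
#' @examples
#' bundle <- makeStaticFixtures()[["F1_plus_1exon"]]
#' dir <- tempfile(); dir.create(dir)
#' paths <- writeFixtureBundle(bundle, dir)
#' txs <- loadTranscripts(paths["gtf"], paths["fasta"])
#' txs[[1]]
#' @export
loadTranscripts <- function(gtfPath, genome, verbose = TRUE) {
    if (!file.exists(gtfPath))
        stop("GTF file not found: ", gtfPath)
    genome <- .asGenome(genome)
    gtf <- rtracklayer::import(gtfPath, format = "gtf")
    keep <- gtf$type %in% c("exon", "CDS", "start_codon")
    gtf <- gtf[keep]
    if (length(gtf) == 0L) return(list())
    txIds <- unique(gtf$transcript_id[!is.na(gtf$transcript_id)])
    chroms <- .genomeSeqnames(genome)

    models <- list()
    for (txId in txIds) {
        feat <- gtf[!is.na(gtf$transcript_id) & gtf$transcript_id == txId]
        tm <- tryCatch(
            .buildTranscriptModel(txId, feat, chroms),
            uorfSkip = function(e) {
                warning("skipping transcript ", txId, ": ",
                        conditionMessage(e), call. = FALSE)
                NULL
            })
        if (!is.null(tm)) models[[txId]] <- tm
    }
    .msg(verbose, "loaded ", length(models), " transcript model(s) from ",
         basename(gtfPath))
    models
}

.skip <- function(...) {
    stop(structure(class = c("uorfSkip", "error", "condition"),
                   list(message = paste0(...), call = NULL)))
}

.buildTranscriptModel <- function(txId, feat, chroms) {
    exons <- feat[feat$type == "exon"]
    cds <- feat[feat$type == "CDS"]
    startCodon <- feat[feat$type == "start_codon"]
    if (length(exons) == 0L) .skip("no exon features")
    if (length(cds) == 0L && length(startCodon) == 0L)
        .skip("CDS start cannot be located (no CDS features)")
    chrom <- as.character(GenomicRanges::seqnames(exons)[1L])
    strand <- as.character(GenomicRanges::strand(exons)[1L])
    if (!strand %in% c("+", "-")) .skip("unstranded transcript")
    if (!chrom %in% chroms)
        .skip("chromosome ", chrom, " absent from FASTA")

    ord <- order(GenomicRanges::start(exons),
                 decreasing = (strand == "-"))
    exons <- exons[ord]
    cdsStart <- if (length(startCodon) > 0L) {
        if (strand == "+") min(GenomicRanges::start(startCodon))
        else max(GenomicRanges::end(startCodon))
    } else {
        if (strand == "+") min(GenomicRanges::start(cds))
        else max(GenomicRanges::end(cds))
    }
    est <- GenomicRanges::start(exons); een <- GenomicRanges::end(exons)
    if (!any(cdsStart >= est & cdsStart <= een))
        .skip("CDS start ", cdsStart, " not inside any exon")
    utrLen <- if (strand == "+")
        sum(pmax(0L, pmin(een, cdsStart - 1L) - est + 1L))
    else
        sum(pmax(0L, een - pmax(est, cdsStart + 1L) + 1L))
    if (utrLen == 0L) .skip("5'UTR has length 0")

    geneId <- feat$gene_id[1L]
    geneSymbol <- if ("gene_name" %in% names(S4Vectors::mcols(feat)) &&
                      !is.na(feat$gene_name[1L])) feat$gene_name[1L] else ""
    cdsOrd <- order(GenomicRanges::start(cds), decreasing = (strand == "-"))
    new("TranscriptModel",
        transcriptId = txId,
        geneId = if (is.na(geneId)) "" else geneId,
        geneSymbol = geneSymbol,
        chrom = chrom, strand = strand,
        exons = GenomicRanges::granges(exons),
        cdsStart = as.integer(cdsStart),
        cdsIntervals = GenomicRanges::granges(cds[cdsOrd]))
}

#' Extract the spliced 5'UTR (and CDS context) of a transcript
#'
#' Concatenates exonic sequence in transcript orientation, reverse
#' complementing minus-strand transcripts so that offset 0 is always the
#' cap-proximal base, then splits at the annotated start codon. Soft-masked
#' bases are uppercased; \code{N} bases propagate and can never form an AUG
#' or a stop codon.
#'
#' @param tx a \linkS4class{TranscriptModel}.
#' @param genome as in \code{\link{loadTranscripts}}.
#' @param cdsContextLength number of spliced CDS nt retained downstream of
#'   the start codon (stop-scan horizon for overlapping ORFs); truncated at
#'   the transcript end.
#' @return a \linkS4class{SplicedUTR}.
#' @export
extractSplicedUTR <- function(tx, genome, cdsContextLength = 999L) {
    genome <- .asGenome(genome)
    est <- GenomicRanges::start(tx@exons)
    een <- GenomicRanges::end(tx@exons)
    ## genomic-ascending order for sequence fetch and position runs
    ga <- order(est)
    pieces <- character(length(ga)); posRuns <- vector("list", length(ga))
    for (k in seq_along(ga)) {
        i <- ga[k]
        pieces[k] <- tryCatch(
            .fetchSeq(genome, tx@chrom, est[i], een[i]),
            error = function(e) stop("genome lookup failed for transcript ",
                tx@transcriptId, ": ", conditionMessage(e)))
        posRuns[[k]] <- seq.int(est[i], een[i])
    }
    txSeq <- paste(pieces, collapse = "")
    pos1 <- unlist(posRuns, use.names = FALSE)
    if (tx@strand == "-") {
        txSeq <- .revcomp(txSeq)
        pos1 <- rev(pos1)
    }
    idx <- match(tx@cdsStart, pos1)
    if (is.na(idx))
        stop("CDS start not within exons of ", tx@transcriptId)
    utrLen <- idx - 1L
    if (utrLen < 1L)
        stop("transcript ", tx@transcriptId, " has no 5'UTR")
    new("SplicedUTR",
        transcriptId = tx@transcriptId,
        chrom = tx@chrom, strand = tx@strand,
        sequence = substr(txSeq, 1L, utrLen),
        cdsContext = substr(txSeq, utrLen + 1L,
                            min(nchar(txSeq), utrLen + cdsContextLength)),
        genomicPositions = pos1[seq_len(utrLen)] - 1L)
}

#' Map a genomic position to a 5'UTR offset
#'
#' @param utr a \linkS4class{SplicedUTR}.
#' @param genomicPos integer vector of 0-based genomic positions.
#' @return integer vector of 0-based UTR offsets; \code{NA} where the
#'   position is intronic or outside the UTR.
#' @export
genomicToUtrOffset <- function(utr, genomicPos) {
    match(as.integer(genomicPos), utr@genomicPositions) - 1L
}
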