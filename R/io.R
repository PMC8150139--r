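## VCF reading, annotated output (TSV and VCF with a UTRA INFO key), and
## the end-to-end runner.

## read a VCF into per-alt records (multi-allelic records are decomposed
## into per-alt pseudo-records before normalization)
.readVcfRecords <- function(vcfPath) {
    ## htslib wants plain or bgzip input; plain-gzip VCFs are decompressed
    magic <- readBin(vcfPath, "raw", n = 2L)
    if (identical(as.integer(magic), c(31L, 139L))) {
        tmp <- tempfile(fileext = ".vcf")
        writeLines(readLines(vcfPath), tmp)   # readLines inflates gzip
        vcfPath <- tmp
    }
    vcf <- VariantAnnotation::readVcf(vcfPath, genome = "unknown")
    altList <- VariantAnnotation::alt(vcf)
    nAlt <- S4Vectors::elementNROWS(altList)
    srcIdx <- rep(seq_along(nAlt), nAlt)
    rr <- SummarizedExperiment::rowRanges(vcf)
    list(chrom = as.character(GenomicRanges::seqnames(rr))[srcIdx],
         pos = GenomicRanges::start(rr)[srcIdx],
         ref = as.character(VariantAnnotation::ref(vcf))[srcIdx],
         alt = as.character(unlist(altList, use.names = FALSE)),
         srcIdx = srcIdx,
         nRecords = length(nAlt))
}

## reduced genomic ranges of each transcript's UTR exonic bases
.utrRangesIndex <- function(utrs) {
    grl <- lapply(seq_along(utrs), function(i) {
        u <- utrs[[i]]
        r <- IRanges::reduce(IRanges::IRanges(u@genomicPositions + 1L,
                                              width = 1L))
        GenomicRanges::GRanges(u@chrom, r, txIdx = i)
    })
    do.call(c, grl)
}

#' Annotate a VCF of variants for uORF-perturbing consequences
#'
#' End-to-end driver: loads transcripts from a GTF + genome FASTA, reads a
#' VCF (plain or gzip; multi-allelic records are decomposed), normalizes
#' each allele pair, annotates every variant falling in a spliced 5'UTR
#' with the five consequence detectors, and optionally writes a TSV or an
#' annotated VCF (original records preserved, annotations added under the
#' \code{UTRA} INFO key). Variants with symbolic alleles, reference
#' mismatches, or net length change / substitution length beyond
#' \code{maxIndelLen} are skipped and counted; so are UTR variants spanning
#' a splice junction. Summary counts are logged.
#'
#' @param vcfPath,gtfPath,fastaPath input files.
#' @param evidencePath optional translated-uORF evidence TSV
#'   (see \code{\link{loadEvidence}}).
#' @param geneListPath optional plain-text gene list (one gene per line)
#'   used by the high-impact filter.
#' @param outputPath optional output file; when \code{NULL} nothing is
#'   written.
#' @param outputFormat \code{"tsv"} or \code{"vcf"}.
#' @param maxIndelLen small-variant scope cap, bp.
#' @param cdsScanHorizon stop-scan horizon into the CDS, nt.
#' @param highImpactOnly apply \code{\link{prioritizeHighImpact}} before
#'   writing.
#' @param verbose log progress and summary counts.
#' @return (invisibly) a list with \code{annotations} (the 22-column
#'   data.frame) and \code{summary} (named counts).
#' @export
annotateVcf <- function(vcfPath, gtfPath, fastaPath, evidencePath = NULL,
                        geneListPath = NULL, outputPath = NULL,
                        outputFormat = c("tsv", "vcf"), maxIndelLen = 5L,
                        cdsScanHorizon = 999L, highImpactOnly = FALSE,
                        verbose = TRUE) {
    outputFormat <- match.arg(outputFormat)
    for (p in c(vcfPath, gtfPath, fastaPath))
        if (!file.exists(p)) stop("input file not found: ", p)
    genome <- .asGenome(fastaPath)
    txs <- loadTranscripts(gtfPath, genome, verbose = verbose)
    if (length(txs) == 0L)
        stop("no usable transcripts loaded from ", gtfPath)
    utrs <- lapply(txs, extractSplicedUTR, genome = genome,
                   cdsContextLength = cdsScanHorizon)
    evidence <- if (!is.null(evidencePath))
        loadEvidence(evidencePath, verbose = verbose) else NULL
    geneList <- if (!is.null(geneListPath)) {
        gl <- trimws(readLines(geneListPath))
        gl[nzchar(gl)]
    } else NULL

    recs <- .readVcfRecords(vcfPath)
    n <- length(recs$pos)
    utrIdx <- .utrRangesIndex(utrs)
    qry <- GenomicRanges::GRanges(recs$chrom,
        IRanges::IRanges(pmax(1L, recs$pos - 1L),
                         recs$pos + pmax(nchar(recs$ref) - 1L, 1L)))
    hits <- GenomicRanges::findOverlaps(qry, utrIdx)

    counts <- c(read = n, annotated = 0L, skipped_symbolic = 0L,
                skipped_ref_mismatch = 0L, skipped_over_scope = 0L,
                skipped_junction = 0L, no_utr_consequence = 0L)
    rows <- list(); rowRec <- integer(0)
    for (i in seq_len(n)) {
        v <- tryCatch(
            normalizeVariant(recs$chrom[i], recs$pos[i], recs$ref[i],
                             recs$alt[i]),
            error = function(e) NULL)
        if (is.null(v)) {
            counts["skipped_symbolic"] <- counts["skipped_symbolic"] + 1L
            .msg(verbose, "skipping unsupported allele pair at ",
                 recs$chrom[i], ":", recs$pos[i])
            next
        }
        if (!withinScope(v, maxIndelLen)) {
            counts["skipped_over_scope"] <- counts["skipped_over_scope"] + 1L
            .msg(verbose, "skipping >", maxIndelLen, " bp variant ",
                 v@variantId)
            next
        }
        if (nchar(v@ref) > 0L) {
            gseq <- tryCatch(.fetchSeq(genome, v@chrom, v@pos,
                                       v@pos + nchar(v@ref) - 1L),
                             error = function(e) NA_character_)
            if (is.na(gseq) || gseq != v@ref) {
                counts["skipped_ref_mismatch"] <-
                    counts["skipped_ref_mismatch"] + 1L
                warning("reference mismatch for ", v@variantId,
                        "; variant skipped", call. = FALSE)
                next
            }
        }
        cand <- unique(S4Vectors::mcols(utrIdx)$txIdx[
            S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])
        got <- FALSE; junction <- FALSE
        for (k in sort(cand)) {
            res <- .annotateOne(utrs[[k]], txs[[k]], v, evidence)
            if (inherits(res, "uorfNotApplicable")) {
                if (grepl("junction", attr(res, "reason")))
                    junction <- TRUE
                next
            }
            if (nrow(res) > 0L) {
                rows[[length(rows) + 1L]] <- res
                rowRec <- c(rowRec, rep(recs$srcIdx[i], nrow(res)))
                got <- TRUE
            }
        }
        if (got) counts["annotated"] <- counts["annotated"] + 1L
        else if (junction) {
            counts["skipped_junction"] <- counts["skipped_junction"] + 1L
            .msg(verbose, "variant ", v@variantId,
                 " spans a splice junction; skipped")
        } else counts["no_utr_consequence"] <- counts["no_utr_consequence"] + 1L
    }

    ann <- if (length(rows)) do.call(rbind, rows) else
        cbind(emptyAnnotations(), data.frame(sortStart = integer(0)))
    ## order: VCF record, then transcript, consequence class, start offset
    ord <- order(if (length(rowRec)) rowRec else integer(0),
                 ann$transcript_id,
                 match(ann$consequence, CONSEQUENCE_LEVELS), ann$sortStart)
    ann <- ann[ord, , drop = FALSE]
    recIdx <- if (length(rowRec)) rowRec[ord] else integer(0)
    ann$sortStart <- NULL
    rownames(ann) <- NULL

    if (highImpactOnly && nrow(ann) > 0L) {
        sel <- prioritizeHighImpact(cbind(ann, .i = seq_len(nrow(ann))),
                                    geneList)
        recIdx <- recIdx[sel$.i]
        ann <- sel[, names(ann), drop = FALSE]
        rownames(ann) <- NULL
    }

    .msg(verbose, sprintf(
        "variants read %d | annotated %d | no 5'UTR consequence %d | skipped: symbolic %d, ref mismatch %d, over scope %d, junction %d",
        counts["read"], counts["annotated"], counts["no_utr_consequence"],
        counts["skipped_symbolic"], counts["skipped_ref_mismatch"],
        counts["skipped_over_scope"], counts["skipped_junction"]))

    if (!is.null(outputPath)) {
        if (outputFormat == "tsv") writeAnnotationTsv(ann, outputPath)
        else writeAnnotatedVcf(ann, recIdx, vcfPath, outputPath)
        .msg(verbose, "wrote ", outputPath)
    }
    invisible(list(annotations = ann, summary = counts))
}

#' Write annotation rows as TSV
#'
#' One row per (variant x transcript x consequence x uORF) with the full
#' 22-column schema; inapplicable fields are \code{NA}. An empty input
#' yields a header-only file.
#'
#' @param rows annotation data.frame.
#' @param path output file.
#' @export
writeAnnotationTsv <- function(rows, path) {
    utils::write.table(rows[, ANNOTATION_COLUMNS, drop = FALSE], path,
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE,
        na = "NA")
    invisible(path)
}

.serializeUTRA <- function(rows) {
    cols <- lapply(rows[, ANNOTATION_COLUMNS, drop = FALSE], function(x) {
        x <- as.character(x)
        x[is.na(x)] <- "NA"
        gsub("[|,;=]", "_", x)
    })
    do.call(paste, c(cols, sep = "|"))
}

#' Write an annotated VCF
#'
#' Copies the input VCF verbatim, adding an \code{UTRA} INFO key to every
#' annotated record. The value is a comma-separated list of entries, one
#' per annotation row, each a pipe-delimited list of the TSV columns in
#' order; the characters \code{| , ; =} are replaced by \code{_} inside
#' fields. Unannotated records are untouched.
#'
#' @param rows annotation data.frame.
#' @param recIdx integer vector mapping each row to its (1-based) VCF
#'   record.
#' @param vcfPath the input VCF (plain or gzip).
#' @param path output file.
#' @export
writeAnnotatedVcf <- function(rows, recIdx, vcfPath, path) {
    lines <- readLines(vcfPath)
    isHdr <- startsWith(lines, "#")
    hdr <- lines[isHdr]; body <- lines[!isHdr]
    infoLine <- paste0('##INFO=<ID=UTRA,Number=.,Type=String,',
        'Description="uORF-perturbing consequence annotation: ',
        paste(ANNOTATION_COLUMNS, collapse = "_"), '">')
    chromLine <- which(startsWith(hdr, "#CHROM"))
    hdr <- append(hdr, infoLine, after = chromLine - 1L)
    if (nrow(rows) > 0L) {
        entries <- .serializeUTRA(rows)
        for (r in unique(recIdx)) {
            val <- paste(entries[recIdx == r], collapse = ",")
            f <- strsplit(body[r], "\t", fixed = TRUE)[[1]]
            f[8L] <- if (f[8L] %in% c(".", "")) paste0("UTRA=", val)
                     else paste0(f[8L], ";UTRA=", val)
            body[r] <- paste(f, collapse = "\t")
        }
    }
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Parse UTRA entries back into annotation rows
#'
#' Inverse of \code{\link{writeAnnotatedVcf}}: extracts every \code{UTRA}
#' INFO entry of a VCF written by this package and reconstructs the
#' 22-column annotation table.
#'
#' @param vcfPath an annotated VCF.
#' @return data.frame with the same schema as
#'   \code{\link{annotateVcf}}'s annotations.
#' @export
readAnnotatedVcf <- function(vcfPath) {
    lines <- readLines(vcfPath)
    body <- lines[!startsWith(lines, "#")]
    out <- list()
    for (ln in body) {
        info <- strsplit(ln, "\t", fixed = TRUE)[[1]][8L]
        m <- regmatches(info, regexpr("(?:^|;)UTRA=[^;]*", info))
        if (!length(m)) next
        val <- sub("^;?UTRA=", "", m)
        for (entry in strsplit(val, ",", fixed = TRUE)[[1]]) {
            f <- strsplit(entry, "|", fixed = TRUE)[[1]]
            out[[length(out) + 1L]] <- f
        }
    }
    if (!length(out)) return(emptyAnnotations())
    m <- do.call(rbind, out)
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    names(df) <- ANNOTATION_COLUMNS
    tmpl <- emptyAnnotations()
    for (cn in names(df)) {
        df[[cn]][df[[cn]] == "NA"] <- NA
        df[[cn]] <- switch(class(tmpl[[cn]]),
            integer = as.integer(df[[cn]]),
            logical = as.logical(df[[cn]]),
            df[[cn]])
    }
    df
}
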