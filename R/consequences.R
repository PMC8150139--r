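## ---- annotation row schema -------------------------------------------------

ANNOTATION_COLUMNS <- c(
    "chrom", "pos", "ref", "alt", "transcript_id", "gene_id", "consequence",
    "existing_uORFs", "existing_InFrame_oORFs", "existing_OutOfFrame_oORFs",
    "KozakContext", "KozakStrength", "CapDistanceToStart",
    "StartDistanceToCDS", "StartDistanceToStop", "Type", "AltType",
    "Evidence", "AltStop", "AltStopDistanceToCDS", "FrameWithCDS",
    "NewStopDistanceToCDS")

#' Empty annotation table with the full column schema
#'
#' @return a 0-row data.frame with the 22 output columns, correctly typed.
#' @export
emptyAnnotations <- function() {
    data.frame(
        chrom = character(0), pos = integer(0), ref = character(0),
        alt = character(0), transcript_id = character(0),
        gene_id = character(0), consequence = character(0),
        existing_uORFs = integer(0), existing_InFrame_oORFs = integer(0),
        existing_OutOfFrame_oORFs = integer(0), KozakContext = character(0),
        KozakStrength = character(0), CapDistanceToStart = integer(0),
        StartDistanceToCDS = integer(0), StartDistanceToStop = integer(0),
        Type = character(0), AltType = character(0), Evidence = logical(0),
        AltStop = logical(0), AltStopDistanceToCDS = integer(0),
        FrameWithCDS = character(0), NewStopDistanceToCDS = integer(0),
        stringsAsFactors = FALSE)
}

## one consequence-level row, all optional fields NA unless supplied
.row <- function(census, consequence, kozakContext, kozakStrength, sortStart,
                 CapDistanceToStart = NA_integer_,
                 StartDistanceToCDS = NA_integer_,
                 StartDistanceToStop = NA_integer_,
                 Type = NA_character_, AltType = NA_character_,
                 Evidence = NA, AltStop = NA,
                 AltStopDistanceToCDS = NA_integer_,
                 FrameWithCDS = NA_character_,
                 NewStopDistanceToCDS = NA_integer_) {
    data.frame(
        consequence = consequence,
        existing_uORFs = census@nUorf,
        existing_InFrame_oORFs = census@nInframeOorf,
        existing_OutOfFrame_oORFs = census@nOutofframeOorf,
        KozakContext = kozakContext, KozakStrength = kozakStrength,
        CapDistanceToStart = as.integer(CapDistanceToStart),
        StartDistanceToCDS = as.integer(StartDistanceToCDS),
        StartDistanceToStop = as.integer(StartDistanceToStop),
        Type = Type, AltType = AltType,
        Evidence = as.logical(Evidence), AltStop = as.logical(AltStop),
        AltStopDistanceToCDS = as.integer(AltStopDistanceToCDS),
        FrameWithCDS = FrameWithCDS,
        NewStopDistanceToCDS = as.integer(NewStopDistanceToCDS),
        sortStart = as.integer(sortStart),
        stringsAsFactors = FALSE)
}

## ---- edge rules shared by the five detectors -------------------------------
## An edit is a replacement of refLen bases at 0-based offset e0 by altLen
## bases. Zero-length sides are junctions: a pure insertion has refLen == 0
## (the junction sits between ref offsets e0-1 and e0), a pure deletion has
## altLen == 0 (junction between alt offsets e0-1 and e0).

## does a width-wide window at offset s intersect the edited side?
.windowHitsEdit <- function(s, width, e0, editLen) {
    if (editLen > 0L)
        s <= e0 + editLen - 1L && s + width - 1L >= e0
    else
        s <= e0 - 1L && s + width - 1L >= e0     # straddles the junction
}

## is a ref AUG at s destroyed by the edit?
.augLost <- function(s, e0, nref, nalt, altSeq) {
    hit <- if (nref > 0L) .windowHitsEdit(s, 3L, e0, nref)
           else (e0 >= s + 1L && e0 <= s + 2L)   # insertion inside the AUG
    if (!hit) return(FALSE)
    if (nref == nalt) .sub0(altSeq, s, 3L) != "ATG" else TRUE
}

## is an alt AUG at s newly created by the edit?
.augGained <- function(s, e0, nref, nalt, refSeq) {
    hit <- .windowHitsEdit(s, 3L, e0, nalt)
    if (!hit) return(FALSE)
    if (nref == nalt) .sub0(refSeq, s, 3L) != "ATG" else TRUE
}

## map a ref offset outside the edit to its alt offset
.mapRefToAlt <- function(s, e0, nref, nalt) {
    if (s >= e0 + nref) s + nalt - nref else s
}

## all in-frame stop-codon first-base offsets wholly within seq, from `from`
.inFrameUtrStops <- function(seqStr, from) {
    n <- nchar(seqStr)
    p <- seq.int(from, n, by = 3L)
    p <- p[p + 3L <= n + 0L]
    if (!length(p)) return(integer(0))
    p[vapply(p, function(i) .isStop(.sub0(seqStr, i, 3L)), logical(1))]
}

## start->stop distance convention: first base of stop minus first base of
## start; NA for inframe_oORF (its stop is the CDS stop) and when no stop
## lies within the scan horizon.
.startStopDistance <- function(orf) {
    if (orf$subtype == "inframe_oORF" || is.na(orf$stopOffset))
        NA_integer_
    else orf$stopOffset - orf$startOffset
}

## ---- the five detectors ----------------------------------------------------

#' Annotate a single normalized edit of a spliced 5'UTR
#'
#' The pure core of the consequence engine: given a reference spliced 5'UTR,
#' its CDS context and one normalized edit in transcript coordinates, runs
#' all five consequence detectors (uAUG_gained, uAUG_lost, uSTOP_lost,
#' uSTOP_gained, uFrameshift) and returns the annotation rows. This is the
#' unit validated against the independent brute-force oracle
#' (\code{\link{oracleAnnotateEdit}}).
#'
#' @param utrSequence reference spliced 5'UTR (uppercase, transcript
#'   orientation).
#' @param cdsContext first K nt of spliced CDS (stop-scan horizon).
#' @param editStart 0-based UTR offset of the first replaced base (for pure
#'   insertions, the offset before which bases are inserted).
#' @param refAllele,altAllele trimmed alleles in transcript orientation; one
#'   may be \code{""}.
#' @param evidenceFn function(startOffset) -> logical, translation evidence
#'   for the reference uORF starting at that offset.
#' @return data.frame of consequence rows (plus a \code{sortStart} helper
#'   column), sorted by consequence class then start offset.
#' @export
annotateUTREdit <- function(utrSequence, cdsContext, editStart, refAllele,
                            altAllele, evidenceFn = function(s) FALSE) {
    e0 <- as.integer(editStart)
    nref <- nchar(refAllele); nalt <- nchar(altAllele)
    stopifnot(nref > 0L || nalt > 0L)
    if (nref > 0L && .sub0(utrSequence, e0, nref) != refAllele)
        stop("refAllele does not match the UTR at offset ", e0)
    refLen <- nchar(utrSequence)
    altSeq <- paste0(substr(utrSequence, 1L, e0), altAllele,
                     substr(utrSequence, e0 + nref + 1L, refLen))
    altLen <- nchar(altSeq)
    census <- uorfCensus(utrSequence, cdsContext)
    recs <- census@records
    rows <- list()

    ## (i) uAUG_gained: new AUGs in the alt UTR
    for (s in findUaugs(altSeq)) {
        if (!.augGained(s, e0, nref, nalt, utrSequence)) next
        orf <- scanOrf(s, altSeq, cdsContext)
        koz <- kozakAssess(altSeq, cdsContext, s)
        rows[[length(rows) + 1L]] <- .row(census, "uAUG_gained",
            koz$context, koz$strength, sortStart = s,
            CapDistanceToStart = s,
            StartDistanceToCDS = altLen - s,
            StartDistanceToStop = .startStopDistance(orf),
            Type = orf$subtype)
    }

    for (i in seq_len(nrow(recs))) {
        s <- recs$startOffset[i]
        t <- recs$stopOffset[i]
        lost <- .augLost(s, e0, nref, nalt, altSeq)
        ev <- isTRUE(evidenceFn(s))

        ## (ii) uAUG_lost: reference AUGs destroyed by the edit
        if (lost) {
            orf <- list(startOffset = s, stopOffset = t,
                        subtype = recs$subtype[i])
            rows[[length(rows) + 1L]] <- .row(census, "uAUG_lost",
                recs$kozakContext[i], recs$kozakStrength[i], sortStart = s,
                StartDistanceToCDS = refLen - s,
                StartDistanceToStop = .startStopDistance(orf),
                Type = recs$subtype[i], Evidence = ev)
            next    # a destroyed start cannot also lose/gain stops or shift
        }
        sAlt <- .mapRefToAlt(s, e0, nref, nalt)

        ## (iii) uSTOP_lost: the uORF's own stop codon is edited away
        if (recs$subtype[i] == "uORF" &&
            .windowHitsEdit(t, 3L, e0, nref) &&
            (if (nref == nalt) !.isStop(.sub0(altSeq, t, 3L)) else TRUE)) {
            searchFrom <- if (nref == nalt) t + 1L else e0 + nalt
            altStops <- .inFrameUtrStops(altSeq, sAlt)
            altStops <- altStops[altStops >= searchFrom]
            if (length(altStops)) {
                rows[[length(rows) + 1L]] <- .row(census, "uSTOP_lost",
                    recs$kozakContext[i], recs$kozakStrength[i],
                    sortStart = s, Evidence = ev, AltStop = TRUE,
                    AltStopDistanceToCDS = altLen - altStops[1L])
            } else {
                rows[[length(rows) + 1L]] <- .row(census, "uSTOP_lost",
                    recs$kozakContext[i], recs$kozakStrength[i],
                    sortStart = s, Evidence = ev, AltStop = FALSE,
                    FrameWithCDS = if ((altLen - sAlt) %% 3L == 0L)
                        "inFrame" else "outOfFrame")
            }
        }

        ## (iv) uSTOP_gained: the alt frame walk meets an earlier stop
        altStops <- .inFrameUtrStops(altSeq, sAlt)
        if (length(altStops)) {
            tNew <- altStops[1L]
            tOldAlt <- if (recs$subtype[i] == "uORF") {
                if (t >= e0 + nref) t + nalt - nref else e0 + nalt
            } else NA_integer_
            earlier <- if (recs$subtype[i] == "uORF") tNew < tOldAlt else TRUE
            if (earlier && .windowHitsEdit(tNew, 3L, e0, nalt)) {
                rows[[length(rows) + 1L]] <- .row(census, "uSTOP_gained",
                    recs$kozakContext[i], recs$kozakStrength[i],
                    sortStart = s, StartDistanceToCDS = refLen - s,
                    Type = recs$subtype[i], Evidence = ev,
                    NewStopDistanceToCDS = altLen - tNew)
            }
        }

        ## (v) uFrameshift: non-multiple-of-three indel inside the ORF body
        if (nref != nalt && (abs(nref - nalt) %% 3L) != 0L) {
            bodyEnd <- if (recs$stopInUtr[i]) t + 2L else refLen - 1L
            hit <- if (nref > 0L)
                e0 <= bodyEnd && e0 + nref - 1L >= s
            else e0 >= s + 1L && e0 <= bodyEnd
            if (hit) {
                altOrf <- scanOrf(sAlt, altSeq, cdsContext)
                rows[[length(rows) + 1L]] <- .row(census, "uFrameshift",
                    recs$kozakContext[i], recs$kozakStrength[i],
                    sortStart = s, StartDistanceToCDS = altLen - sAlt,
                    Type = recs$subtype[i], AltType = altOrf$subtype,
                    Evidence = ev)
            }
        }
    }

    out <- if (length(rows)) do.call(rbind, rows) else
        cbind(emptyAnnotations()[, -seq_len(6L)],
              data.frame(sortStart = integer(0)))
    ord <- order(match(out$consequence, CONSEQUENCE_LEVELS), out$sortStart)
    out[ord, , drop = FALSE]
}

## ---- per-variant driver ----------------------------------------------------

## annotate one (variant, transcript) pair; utr precomputed by the caller
.annotateOne <- function(utr, tx, v, evidenceStore = NULL) {
    app <- applyVariant(utr, v)
    if (inherits(app, "uorfNotApplicable")) return(app)
    evidenceFn <- if (is.null(evidenceStore)) function(s) FALSE
        else function(s) hasEvidenceAt(evidenceStore, utr@chrom,
            utr@genomicPositions[s + 1L] + 1L, utr@strand)
    rows <- annotateUTREdit(utr@sequence, utr@cdsContext, app$editStart,
                            app$utrRef, app$utrAlt, evidenceFn)
    if (nrow(rows) == 0L) return(emptyAnnotations())
    id <- data.frame(
        chrom = v@chrom, pos = v@pos, ref = v@ref, alt = v@alt,
        transcript_id = tx@transcriptId, gene_id = tx@geneId,
        stringsAsFactors = FALSE)
    out <- cbind(id[rep(1L, nrow(rows)), , drop = FALSE], rows)
    rownames(out) <- NULL
    out
}

#' Annotate one variant against a set of transcript models
#'
#' Runs all five consequence detectors for every transcript whose spliced
#' 5'UTR contains the variant, emitting one row per
#' (transcript x consequence x uORF). A variant overlapping no 5'UTR yields
#' an empty table. Rows are sorted by transcript, consequence class
#' (gained, lost, stop_lost, stop_gained, frameshift) and start offset for
#' byte-stable output.
#'
#' @param txModels list of \linkS4class{TranscriptModel} (or a precomputed
#'   list of \linkS4class{SplicedUTR} via \code{utrs}).
#' @param v a \linkS4class{VariantRecord}.
#' @param genome as in \code{\link{loadTranscripts}}.
#' @param evidenceStore optional \linkS4class{EvidenceStore}.
#' @param cdsContextLength stop-scan horizon, nt.
#' @param utrs optional named list of precomputed SplicedUTR objects
#'   parallel to \code{txModels} (avoids re-extraction in loops).
#' @return data.frame of annotation rows (22-column schema).
#' @export
annotateVariant <- function(txModels, v, genome, evidenceStore = NULL,
                            cdsContextLength = 999L, utrs = NULL) {
    if (is.null(utrs)) {
        genome <- .asGenome(genome)
        utrs <- lapply(txModels, extractSplicedUTR, genome = genome,
                       cdsContextLength = cdsContextLength)
    }
    out <- list()
    for (i in seq_along(txModels)) {
        res <- .annotateOne(utrs[[i]], txModels[[i]], v, evidenceStore)
        if (!inherits(res, "uorfNotApplicable") && nrow(res) > 0L)
            out[[length(out) + 1L]] <- res
    }
    if (!length(out)) return(emptyAnnotations())
    res <- do.call(rbind, out)
    res <- res[order(res$transcript_id,
                     match(res$consequence, CONSEQUENCE_LEVELS),
                     res$sortStart), , drop = FALSE]
    rownames(res) <- NULL
    res$sortStart <- NULL
    res
}

#' Filter annotation rows to high-impact candidates
#'
#' Keeps rows whose variant forms a new overlapping ORF (oORF) with a
#' Strong or Moderate Kozak start site — a uAUG_gained with oORF subtype, a
#' uSTOP_lost with no alternative stop, or a uFrameshift whose alt subtype
#' is an oORF — or that disrupt a uORF with documented evidence of
#' translation. When a gene list is supplied, rows are additionally
#' restricted to those genes (matched against \code{gene_id}).
#'
#' @param rows annotation data.frame from \code{\link{annotateVariant}}.
#' @param geneList character vector of gene identifiers; empty or NULL
#'   skips the gene filter.
#' @return the filtered data.frame.
#' @export
prioritizeHighImpact <- function(rows, geneList = NULL) {
    if (nrow(rows) == 0L) return(rows)
    formsOorf <-
        (rows$consequence == "uAUG_gained" & rows$Type %in% OORF_SUBTYPES) |
        (rows$consequence == "uSTOP_lost" & !is.na(rows$AltStop) &
             !rows$AltStop) |
        (rows$consequence == "uFrameshift" & rows$AltType %in% OORF_SUBTYPES)
    condA <- formsOorf & rows$KozakStrength %in% c("Strong", "Moderate")
    condB <- !is.na(rows$Evidence) & rows$Evidence
    keep <- condA | condB
    if (!is.null(geneList) && length(geneList) > 0L)
        keep <- keep & rows$gene_id %in% geneList
    out <- rows[keep, , drop = FALSE]
    rownames(out) <- NULL
    out
}
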