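## Independent brute-force oracle for the consequence engine.
##
## Everything here re-derives ORF structure from first principles on
## character vectors, deliberately sharing no scanning or classification
## code with the engine in consequences.R / uorf-scanner.R. The boundary
## rules for edit overlap under indels are the package's documented
## contract and are therefore encoded here a second time, independently.

.oChars <- function(x) if (nchar(x)) strsplit(x, "", fixed = TRUE)[[1]] else character(0)

.oIsStop <- function(triplet) triplet %in% c("TAA", "TAG", "TGA")

## 1-based indices of every ATG in a character vector
.oAugs <- function(ch) {
    n <- length(ch)
    if (n < 3L) return(integer(0))
    out <- integer(0)
    for (i in seq_len(n - 2L))
        if (ch[i] == "A" && ch[i + 1L] == "T" && ch[i + 2L] == "G")
            out <- c(out, i)
    out
}

## walk an ORF from 1-based index i1 over utr chars + context chars
.oOrf <- function(utrCh, ctxCh, i1) {
    full <- c(utrCh, ctxCh)
    L <- length(utrCh)
    j <- i1; stop1 <- NA_integer_; inUtr <- FALSE
    while (j + 2L <= length(full)) {
        if (.oIsStop(paste(full[j:(j + 2L)], collapse = ""))) {
            stop1 <- j
            inUtr <- (j + 2L) <= L
            break
        }
        j <- j + 3L
    }
    subtype <- if (inUtr) "uORF"
        else if ((L - (i1 - 1L)) %% 3L == 0L) "inframe_oORF"
        else "OutOfFrame_oORF"
    list(stop1 = stop1, inUtr = inUtr, subtype = subtype)
}

.oKozak <- function(utrCh, ctxCh, i1) {
    full <- c(utrCh, ctxCh)
    idx <- (i1 - 3L):(i1 + 3L)
    ctx <- ifelse(idx < 1L | idx > length(full), "N", full[pmax(idx, 1L)])
    ctx <- paste(ctx, collapse = "")
    a <- substr(ctx, 1L, 1L) %in% c("A", "G")
    b <- substr(ctx, 7L, 7L) == "G"
    list(context = ctx,
         strength = if (a && b) "Strong" else if (a || b) "Moderate"
                    else "Weak")
}

## all 1-based in-frame stop indices wholly inside utrCh, walking from from1
.oInFrameStops <- function(utrCh, from1) {
    out <- integer(0)
    j <- from1
    while (j + 2L <= length(utrCh)) {
        if (.oIsStop(paste(utrCh[j:(j + 2L)], collapse = "")))
            out <- c(out, j)
        j <- j + 3L
    }
    out
}

.oRow <- function(counts, consequence, kozak, sortStart,
                  CapDistanceToStart = NA, StartDistanceToCDS = NA,
                  StartDistanceToStop = NA, Type = NA_character_,
                  AltType = NA_character_, Evidence = NA, AltStop = NA,
                  AltStopDistanceToCDS = NA, FrameWithCDS = NA_character_,
                  NewStopDistanceToCDS = NA) {
    data.frame(consequence = consequence,
        existing_uORFs = counts[["uORF"]],
        existing_InFrame_oORFs = counts[["inframe_oORF"]],
        existing_OutOfFrame_oORFs = counts[["OutOfFrame_oORF"]],
        KozakContext = kozak$context, KozakStrength = kozak$strength,
        CapDistanceToStart = as.integer(CapDistanceToStart),
        StartDistanceToCDS = as.integer(StartDistanceToCDS),
        StartDistanceToStop = as.integer(StartDistanceToStop),
        Type = Type, AltType = AltType, Evidence = as.logical(Evidence),
        AltStop = as.logical(AltStop),
        AltStopDistanceToCDS = as.integer(AltStopDistanceToCDS),
        FrameWithCDS = FrameWithCDS,
        NewStopDistanceToCDS = as.integer(NewStopDistanceToCDS),
        sortStart = as.integer(sortStart), stringsAsFactors = FALSE)
}

## distance convention shared with the engine contract
.oStartStop <- function(i1, orf) {
    if (orf$subtype == "inframe_oORF" || is.na(orf$stop1)) NA_integer_
    else orf$stop1 - i1
}

#' Brute-force oracle annotation of a single 5'UTR edit
#'
#' Independent reference implementation of the five consequence detectors,
#' used to validate \code{\link{annotateUTREdit}} on random fixtures. It
#' enumerates every (start, stop, subtype) triple in the reference and
#' alternate UTR by exhaustive character-level scanning and classifies the
#' differences by first principles, using the same documented boundary
#' rules but none of the engine's code.
#'
#' @inheritParams annotateUTREdit
#' @return data.frame with the same columns and ordering as
#'   \code{\link{annotateUTREdit}}.
#' @export
oracleAnnotateEdit <- function(utrSequence, cdsContext, editStart, refAllele,
                               altAllele, evidenceFn = function(s) FALSE) {
    e0 <- as.integer(editStart)
    nref <- nchar(refAllele); nalt <- nchar(altAllele)
    refCh <- .oChars(utrSequence)
    ctxCh <- .oChars(cdsContext)
    altCh <- c(if (e0 > 0L) refCh[seq_len(e0)], .oChars(altAllele),
               if (e0 + nref < length(refCh))
                   refCh[(e0 + nref + 1L):length(refCh)])
    refLen <- length(refCh); altLen <- length(altCh)
    lenPreserving <- (nref == nalt)

    ## reference census by exhaustive enumeration
    refAugs <- .oAugs(refCh)
    refOrfs <- lapply(refAugs, function(i1) .oOrf(refCh, ctxCh, i1))
    subtypes <- vapply(refOrfs, `[[`, "", "subtype")
    counts <- c(uORF = sum(subtypes == "uORF"),
                inframe_oORF = sum(subtypes == "inframe_oORF"),
                OutOfFrame_oORF = sum(subtypes == "OutOfFrame_oORF"))

    hitsRef <- function(s0, w) {
        if (nref > 0L) s0 <= e0 + nref - 1L && s0 + w - 1L >= e0
        else e0 >= s0 + 1L && e0 <= s0 + w - 1L
    }
    hitsAlt <- function(s0, w) {
        if (nalt > 0L) s0 <= e0 + nalt - 1L && s0 + w - 1L >= e0
        else s0 <= e0 - 1L && s0 + w - 1L >= e0
    }
    tripletAt <- function(ch, s0) paste(ch[(s0 + 1L):(s0 + 3L)], collapse = "")

    rows <- list()

    ## uAUG_gained
    for (a1 in .oAugs(altCh)) {
        s0 <- a1 - 1L
        if (!hitsAlt(s0, 3L)) next
        if (lenPreserving && s0 + 3L <= refLen &&
            tripletAt(refCh, s0) == "ATG") next
        orf <- .oOrf(altCh, ctxCh, a1)
        rows[[length(rows) + 1L]] <- .oRow(counts, "uAUG_gained",
            .oKozak(altCh, ctxCh, a1), sortStart = s0,
            CapDistanceToStart = s0, StartDistanceToCDS = altLen - s0,
            StartDistanceToStop = .oStartStop(a1, orf), Type = orf$subtype)
    }

    for (k in seq_along(refAugs)) {
        i1 <- refAugs[k]; s0 <- i1 - 1L
        orf <- refOrfs[[k]]
        koz <- .oKozak(refCh, ctxCh, i1)
        ev <- isTRUE(evidenceFn(s0))
        lost <- hitsRef(s0, 3L) &&
            (!lenPreserving || tripletAt(altCh, s0) != "ATG")
        if (lost) {
            rows[[length(rows) + 1L]] <- .oRow(counts, "uAUG_lost", koz,
                sortStart = s0, StartDistanceToCDS = refLen - s0,
                StartDistanceToStop = .oStartStop(i1, orf),
                Type = orf$subtype, Evidence = ev)
            next
        }
        sAlt0 <- if (s0 >= e0 + nref) s0 + nalt - nref else s0
        altStops0 <- .oInFrameStops(altCh, sAlt0 + 1L) - 1L

        if (orf$subtype == "uORF") {
            t0 <- orf$stop1 - 1L
            destroyed <- hitsRef(t0, 3L) &&
                (!lenPreserving || !.oIsStop(tripletAt(altCh, t0)))
            if (destroyed) {
                from <- if (lenPreserving) t0 + 1L else e0 + nalt
                cand <- altStops0[altStops0 >= from]
                if (length(cand)) {
                    rows[[length(rows) + 1L]] <- .oRow(counts, "uSTOP_lost",
                        koz, sortStart = s0, Evidence = ev, AltStop = TRUE,
                        AltStopDistanceToCDS = altLen - cand[1L])
                } else {
                    rows[[length(rows) + 1L]] <- .oRow(counts, "uSTOP_lost",
                        koz, sortStart = s0, Evidence = ev, AltStop = FALSE,
                        FrameWithCDS = if ((altLen - sAlt0) %% 3L == 0L)
                            "inFrame" else "outOfFrame")
                }
            }
        }

        if (length(altStops0)) {
            tNew0 <- altStops0[1L]
            earlier <- if (orf$subtype == "uORF") {
                t0 <- orf$stop1 - 1L
                tOldAlt0 <- if (t0 >= e0 + nref) t0 + nalt - nref
                            else e0 + nalt
                tNew0 < tOldAlt0
            } else TRUE
            if (earlier && hitsAlt(tNew0, 3L)) {
                rows[[length(rows) + 1L]] <- .oRow(counts, "uSTOP_gained",
                    koz, sortStart = s0, StartDistanceToCDS = refLen - s0,
                    Type = orf$subtype, Evidence = ev,
                    NewStopDistanceToCDS = altLen - tNew0)
            }
        }

        if (nref != nalt && (abs(nref - nalt) %% 3L) != 0L) {
            bodyEnd0 <- if (orf$inUtr) orf$stop1 + 1L else refLen - 1L
            hit <- if (nref > 0L) e0 <= bodyEnd0 && e0 + nref - 1L >= s0
                   else e0 >= s0 + 1L && e0 <= bodyEnd0
            if (hit) {
                altOrf <- .oOrf(altCh, ctxCh, sAlt0 + 1L)
                rows[[length(rows) + 1L]] <- .oRow(counts, "uFrameshift",
                    koz, sortStart = s0,
                    StartDistanceToCDS = altLen - sAlt0,
                    Type = orf$subtype, AltType = altOrf$subtype,
                    Evidence = ev)
            }
        }
    }

    out <- if (length(rows)) do.call(rbind, rows) else
        .oRow(c(uORF = 0L, inframe_oORF = 0L, OutOfFrame_oORF = 0L), "x",
              list(context = "x", strength = "x"), 0L)[0L, ]
    lev <- c("uAUG_gained", "uAUG_lost", "uSTOP_lost", "uSTOP_gained",
             "uFrameshift")
    out <- out[order(match(out$consequence, lev), out$sortStart), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}
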