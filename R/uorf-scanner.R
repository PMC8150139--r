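#' UorfCensus: the (u)ORF content of one 5'UTR
#'
#' Per-AUG records and subtype counts for a reference 5'UTR. Each AUG
#' defines its own (u)ORF even when several share a stop codon, because each
#' start site is independently perturbable; the counts therefore sum to the
#' number of AUGs in the UTR.
#'
#' @slot records data.frame with one row per AUG: \code{startOffset},
#'   \code{stopOffset} (concatenated UTR+CDS-context offset of the stop's
#'   first base, \code{NA} if none within the horizon), \code{stopInUtr},
#'   \code{subtype}, \code{kozakContext}, \code{kozakStrength}.
#' @slot nUorf,nInframeOorf,nOutofframeOorf integer counts by subtype.
#'
#' @exportClass UorfCensus
setClass("UorfCensus",
    representation(records = "data.frame", nUorf = "integer",
                   nInframeOorf = "integer", nOutofframeOorf = "integer"))

setMethod("show", "UorfCensus", function(object) {
    cat(sprintf("UorfCensus: %d uORF, %d inframe_oORF, %d OutOfFrame_oORF\n",
        object@nUorf, object@nInframeOorf, object@nOutofframeOorf))
})

#' Find all AUG triplets in a sequence
#'
#' @param sequence uppercase DNA string.
#' @return ascending integer vector of 0-based offsets of the A of each ATG.
#' @examples
#' findUaugs("ATGTGATG")  # 0 and 5
#' @export
findUaugs <- function(sequence) {
    if (nchar(sequence) < 3L) return(integer(0))
    hits <- Biostrings::matchPattern("ATG",
        Biostrings::DNAString(sequence), fixed = TRUE)
    sort(Biostrings::start(hits)) - 1L
}

#' Walk an ORF from an AUG and classify its subtype
#'
#' Reads codons from \code{startOffset}. The first of TAA/TAG/TGA wholly
#' inside the UTR makes the ORF a distinct \code{uORF}; a codon straddling
#' the UTR/CDS junction counts as not-in-UTR. Without a UTR stop, scanning
#' continues into \code{cdsContext} up to its end (the horizon) and the ORF
#' is an overlapping ORF: \code{inframe_oORF} when
#' \code{(utr_length - startOffset) \%\% 3 == 0} (an N-terminal extension),
#' else \code{OutOfFrame_oORF}.
#'
#' @param startOffset 0-based UTR offset of an ATG.
#' @param utrSequence,cdsContext uppercase DNA strings.
#' @return list with \code{startOffset}, \code{stopOffset} (0-based offset of
#'   the stop's first base in the concatenated UTR+context sequence, or
#'   \code{NA} when no stop lies within the horizon), \code{stopInUtr} and
#'   \code{subtype}.
#' @export
scanOrf <- function(startOffset, utrSequence, cdsContext = "") {
    utrLen <- nchar(utrSequence)
    if (.sub0(utrSequence, startOffset, 3L) != "ATG")
        stop("no ATG at offset ", startOffset)
    full <- paste0(utrSequence, cdsContext)
    n <- nchar(full)
    i <- startOffset
    stopOffset <- NA_integer_; stopInUtr <- FALSE
    while (i + 3L <= n) {
        codon <- .sub0(full, i, 3L)
        if (.isStop(codon)) {
            stopOffset <- i
            stopInUtr <- (i + 3L <= utrLen)
            break
        }
        i <- i + 3L
    }
    subtype <- if (stopInUtr) "uORF"
        else if ((utrLen - startOffset) %% 3L == 0L) "inframe_oORF"
        else "OutOfFrame_oORF"
    list(startOffset = startOffset, stopOffset = stopOffset,
         stopInUtr = stopInUtr, subtype = subtype)
}

#' Assess the Kozak context of an AUG
#'
#' Assembles the 7-character context covering positions -3..+4 of an AUG
#' (the AUG occupies characters 4-6) from the concatenation of the UTR and
#' its CDS context, padding positions upstream of the cap with \code{N}.
#' Strength follows the classical two-feature rule: \code{Strong} when the
#' -3 base is a purine (A/G) and the +4 base is G, \code{Moderate} when
#' exactly one of the two holds, \code{Weak} otherwise (an \code{N} fails
#' both tests).
#'
#' @inheritParams scanOrf
#' @return list with \code{context} (7 characters) and \code{strength}.
#' @examples
#' kozakAssess("GCCATGAAATAGCCGGCTTTCCGGCAAGGC", "ATGGCTGCATAA", 3)
#' @export
kozakAssess <- function(utrSequence, cdsContext, startOffset) {
    full <- paste0(utrSequence, cdsContext)
    chars <- vapply(startOffset - 3L + 0:6, function(p) {
        if (p < 0L || p >= nchar(full)) "N" else .sub0(full, p, 1L)
    }, character(1))
    context <- paste(chars, collapse = "")
    m3ok <- chars[1L] %in% c("A", "G")
    p4ok <- chars[7L] == "G"
    strength <- if (m3ok && p4ok) "Strong"
        else if (m3ok || p4ok) "Moderate" else "Weak"
    list(context = context, strength = strength)
}

#' Census of (u)ORFs in a reference 5'UTR
#'
#' Enumerates every AUG in the UTR, walks its ORF with \code{\link{scanOrf}}
#' and scores its Kozak context, then counts subtypes.
#'
#' @inheritParams scanOrf
#' @return a \linkS4class{UorfCensus}.
#' @export
uorfCensus <- function(utrSequence, cdsContext = "") {
    starts <- findUaugs(utrSequence)
    rec <- lapply(starts, function(s) {
        orf <- scanOrf(s, utrSequence, cdsContext)
        koz <- kozakAssess(utrSequence, cdsContext, s)
        data.frame(startOffset = s, stopOffset = orf$stopOffset,
                   stopInUtr = orf$stopInUtr, subtype = orf$subtype,
                   kozakContext = koz$context, kozakStrength = koz$strength,
                   stringsAsFactors = FALSE)
    })
    records <- if (length(rec)) do.call(rbind, rec)
        else data.frame(startOffset = integer(0), stopOffset = integer(0),
                        stopInUtr = logical(0), subtype = character(0),
                        kozakContext = character(0),
                        kozakStrength = character(0))
    new("UorfCensus", records = records,
        nUorf = sum(records$subtype == "uORF"),
        nInframeOorf = sum(records$subtype == "inframe_oORF"),
        nOutofframeOorf = sum(records$subtype == "OutOfFrame_oORF"))
}
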