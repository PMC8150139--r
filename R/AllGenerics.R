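#' @rdname accessors
#' @export
setGeneric("transcriptId", function(x) standardGeneric("transcriptId"))

#' @rdname accessors
#' @export
setGeneric("utrSequence", function(x) standardGeneric("utrSequence"))

#' @rdname accessors
#' @export
setGeneric("utrLength", function(x) standardGeneric("utrLength"))

#' @rdname accessors
#' @export
setGeneric("cdsContext", function(x) standardGeneric("cdsContext"))

#' @rdname accessors
#' @export
setGeneric("genomicPositions", function(x) standardGeneric("genomicPositions"))

#' @rdname accessors
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))

#' Accessors for uORFannotate classes
#'
#' Small read-only accessors for the package's S4 classes, preferred over
#' direct slot access.
#'
#' @param x a \linkS4class{TranscriptModel}, \linkS4class{SplicedUTR} or
#'   \linkS4class{VariantRecord}.
#' @return The corresponding slot value; \code{variantClass} returns one of
#'   \code{"SNV"}, \code{"MNV"}, \code{"insertion"}, \code{"deletion"}.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("transcriptId", "TranscriptModel", function(x) x@transcriptId)

#' @rdname accessors
#' @export
setMethod("transcriptId", "SplicedUTR", function(x) x@transcriptId)

#' @rdname accessors
#' @export
setMethod("utrSequence", "SplicedUTR", function(x) x@sequence)

#' @rdname accessors
#' @export
setMethod("utrLength", "SplicedUTR", function(x) nchar(x@sequence))

#' @rdname accessors
#' @export
setMethod("cdsContext", "SplicedUTR", function(x) x@cdsContext)

#' @rdname accessors
#' @export
setMethod("genomicPositions", "SplicedUTR", function(x) x@genomicPositions)

#' @rdname accessors
#' @export
setMethod("variantClass", "VariantRecord", function(x) {
    nr <- nchar(x@ref); na <- nchar(x@alt)
    if (nr == na) {
        if (nr == 1L) "SNV" else "MNV"
    } else if (nr > na) "deletion" else "insertion"
})
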