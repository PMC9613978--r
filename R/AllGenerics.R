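#' Accessors for SyngenMarkers classes
#'
#' @param x An object.
#' @param ... Ignored.
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("markerName", function(x, ...) standardGeneric("markerName"))

#' @rdname accessors
#' @export
setGeneric("recordIds", function(x, ...) standardGeneric("recordIds"))

#' @rdname accessors
#' @export
setGeneric("sequences", function(x, ...) standardGeneric("sequences"))

#' @rdname accessors
#' @export
setGeneric("alignmentLength", function(x, ...) standardGeneric("alignmentLength"))

#' @rdname accessors
#' @export
setGeneric("seqMatrix", function(x, ...) standardGeneric("seqMatrix"))

#' @rdname accessors
#' @export
setGeneric("cladeOf", function(x, ...) standardGeneric("cladeOf"))

#' @rdname accessors
#' @export
setGeneric("cladeLevels", function(x, ...) standardGeneric("cladeLevels"))

#' @rdname accessors
#' @export
setGeneric("signatureEntries", function(x, ...) standardGeneric("signatureEntries"))

#' Diagnostic (marker, column, clade, state) triples of a signature
#'
#' @param x A [SignatureSet-class] or [CombinedSignature-class].
#' @return A data.frame with columns \code{marker}, \code{column},
#'   \code{clade}, \code{state}: one row per clade a column is diagnostic
#'   for.
#' @export
setGeneric("diagnosticTriples", function(x) standardGeneric("diagnosticTriples"))

#' @rdname accessors
#' @export
setGeneric("separability", function(x, ...) standardGeneric("separability"))

#' @rdname accessors
#' @export
setGeneric("hapIds", function(x, ...) standardGeneric("hapIds"))

#' @rdname accessors
#' @export
setGeneric("hapFreq", function(x, ...) standardGeneric("hapFreq"))

#' @rdname accessors
#' @export
setGeneric("hapMembers", function(x, ...) standardGeneric("hapMembers"))

#' @rdname accessors
#' @export
setGeneric("regionCounts", function(x, ...) standardGeneric("regionCounts"))

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x, ...) standardGeneric("networkEdges"))

#' @rdname accessors
#' @export
setGeneric("networkComponents", function(x, ...) standardGeneric("networkComponents"))

#' @rdname accessors
#' @export
setGeneric("limitJ", function(x, ...) standardGeneric("limitJ"))
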