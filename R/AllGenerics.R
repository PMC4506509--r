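#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x a PolrScreen S4 object.
#' @return The slot content (a data.frame, scalar or numeric vector).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("spectralCounts", function(x) standardGeneric("spectralCounts"))

#' @rdname accessors
#' @export
setGeneric("countKind", function(x) standardGeneric("countKind"))

#' @rdname accessors
#' @export
setGeneric("designTable", function(x) standardGeneric("designTable"))

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("librarySize", function(x) standardGeneric("librarySize"))

#' @rdname accessors
#' @export
setGeneric("signalState", function(x) standardGeneric("signalState"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setGeneric("geneClass", function(x) standardGeneric("geneClass"))

#' @rdname accessors
#' @export
setGeneric("nGenes", function(x) standardGeneric("nGenes"))
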