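#' @name skimdist-accessors
#' @title Accessors for skimdist objects
#'
#' @description Small accessor generics for the S4 classes of the
#' package: pattern geometry, sequence-set metadata and the fields of a
#' distance estimate.
#'
#' @param x an object of the documented class.
#' @return the requested field; see the individual methods.
NULL

#' @rdname skimdist-accessors
#' @export
setGeneric("patternLength", function(x) standardGeneric("patternLength"))

#' @rdname skimdist-accessors
#' @export
setGeneric("patternWeight", function(x) standardGeneric("patternWeight"))

#' @rdname skimdist-accessors
#' @export
setGeneric("matchOffsets", function(x) standardGeneric("matchOffsets"))

#' @rdname skimdist-accessors
#' @export
setGeneric("dontCareOffsets", function(x) standardGeneric("dontCareOffsets"))

#' @rdname skimdist-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname skimdist-accessors
#' @export
setGeneric("taxonLabel", function(x) standardGeneric("taxonLabel"))

#' @rdname skimdist-accessors
#' @export
setGeneric("seqRole", function(x) standardGeneric("seqRole"))

#' @rdname skimdist-accessors
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname skimdist-accessors
#' @export
setGeneric("isDefined", function(x) standardGeneric("isDefined"))

#' @rdname skimdist-accessors
#' @export
setGeneric("nMatches", function(x) standardGeneric("nMatches"))

#' @rdname skimdist-accessors
#' @export
setGeneric("rawMismatchRate", function(x) standardGeneric("rawMismatchRate"))

#' @rdname skimdist-accessors
#' @export
setGeneric("correctedMismatchRate",
           function(x) standardGeneric("correctedMismatchRate"))

#' @rdname skimdist-accessors
#' @export
setGeneric("jcDistance", function(x) standardGeneric("jcDistance"))

#' @rdname skimdist-accessors
#' @export
setGeneric("undefinedReason", function(x) standardGeneric("undefinedReason"))
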