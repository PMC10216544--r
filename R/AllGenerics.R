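#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("rearrangements", function(x) standardGeneric("rearrangements"))

#' @rdname accessors
#' @export
setGeneric("repertoires", function(x) standardGeneric("repertoires"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' Translate CDR3 junctions and classify productivity
#'
#' @param x a [CDR3Repertoire-class] or [CDR3Cohort-class].
#' @param ... passed between methods.
#' @return an object of the same class with translation columns filled in.
#' @seealso [translateCdr3()] for the underlying vectorized translator.
#' @export
setGeneric("translateRepertoire",
           function(x, ...) standardGeneric("translateRepertoire"))
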