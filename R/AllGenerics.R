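#' Accessor generics for batmoth classes
#'
#' Small family of accessors used across the package's S4 containers.
#'
#' @param x an object.
#' @param ... further arguments for methods.
#' @return The slot value (see the class documentation for types).
#' @name batmoth-generics
#' @keywords internal
NULL

#' @rdname batmoth-generics
#' @export
setGeneric("interactionId", function(x) standardGeneric("interactionId"))

#' @rdname batmoth-generics
#' @export
setGeneric("mothId", function(x) standardGeneric("mothId"))

#' @rdname batmoth-generics
#' @export
setGeneric("mothSpecies", function(x) standardGeneric("mothSpecies"))

#' @rdname batmoth-generics
#' @export
setGeneric("treatment", function(x) standardGeneric("treatment"))

#' @rdname batmoth-generics
#' @export
setGeneric("outcome", function(x) standardGeneric("outcome"))

#' @rdname batmoth-generics
#' @export
setGeneric("callOnsets", function(x) standardGeneric("callOnsets"))

#' @rdname batmoth-generics
#' @export
setGeneric("callDurations", function(x) standardGeneric("callDurations"))

#' @rdname batmoth-generics
#' @export
setGeneric("clickTimes", function(x) standardGeneric("clickTimes"))

#' @rdname batmoth-generics
#' @export
setGeneric("eventStream", function(x) standardGeneric("eventStream"))

#' @rdname batmoth-generics
#' @export
setGeneric("trajectory", function(x, ...) standardGeneric("trajectory"))

#' @rdname batmoth-generics
#' @export
setGeneric("fractionUnaffected", function(x) standardGeneric("fractionUnaffected"))

#' Evaluate a smoothed flight path
#'
#' @param x a \code{SmoothedPath}.
#' @param t numeric vector of times (s) inside \code{timeRange(x)}.
#' @return \code{positionAt}: an \code{length(t) x 3} matrix of x/y/z
#'   positions (m). \code{velocityAt}: the same shape, first derivatives
#'   (m/s).
#' @name path-evaluation
#' @export
setGeneric("positionAt", function(x, t) standardGeneric("positionAt"))

#' @rdname path-evaluation
#' @export
setGeneric("velocityAt", function(x, t) standardGeneric("velocityAt"))

#' @rdname path-evaluation
#' @export
setGeneric("timeRange", function(x) standardGeneric("timeRange"))
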