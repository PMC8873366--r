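#' Accessor generics
#'
#' Small accessor family used across the package's classes: sampling rate,
#' channel count, underlying numeric matrix, subject identifier, view and
#' accuracy. Prefer these over direct slot access.
#'
#' @param object an object of one of the package's classes.
#' @return The corresponding scalar, vector or matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(object) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(object) standardGeneric("signalMatrix"))

#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("view", function(object) standardGeneric("view"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(object) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("trialTable", function(object) standardGeneric("trialTable"))

#' @rdname accessors
#' @export
setGeneric("fingerprints", function(object) standardGeneric("fingerprints"))
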