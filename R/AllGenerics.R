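#' @import methods
#' @importFrom stats rnorm runif sd cor fft nextn setNames
#' @importFrom utils head tail write.csv read.csv
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x an object.
#' @param value replacement value.
#' @name accessors
#' @return The slot content (see the class documentation).
NULL

#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

#' @rdname accessors
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname accessors
#' @export
setGeneric("burstWidth", function(x) standardGeneric("burstWidth"))

#' @rdname accessors
#' @export
setGeneric("renditions", function(x) standardGeneric("renditions"))

#' @rdname accessors
#' @export
setGeneric("codeKind", function(x) standardGeneric("codeKind"))

#' @rdname accessors
#' @export
setGeneric("feedbackMatrix", function(x) standardGeneric("feedbackMatrix"))

#' @rdname accessors
#' @export
setGeneric("feedbackDelay", function(x) standardGeneric("feedbackDelay"))

#' @rdname accessors
#' @export
setGeneric("mapRank", function(x) standardGeneric("mapRank"))

#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname accessors
#' @export
setGeneric("gated", function(x) standardGeneric("gated"))

#' @rdname accessors
#' @export
setGeneric("gated<-", function(x, value) standardGeneric("gated<-"))

#' @rdname accessors
#' @export
setGeneric("lags", function(x) standardGeneric("lags"))

#' @rdname accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname accessors
#' @export
setGeneric("peakValues", function(x) standardGeneric("peakValues"))

#' @rdname accessors
#' @export
setGeneric("mirrorGains", function(x) standardGeneric("mirrorGains"))
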