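#' @rdname flowEventTable
#' @export
setGeneric("events", function(x, ...) standardGeneric("events"))

#' @rdname flowEventTable
#' @export
setGeneric("channels", function(x, ...) standardGeneric("channels"))

#' @rdname flowEventTable
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname flowEventTable
#' @export
setGeneric("chan", function(x, role) standardGeneric("chan"))

#' @rdname flowEventTable
#' @export
setGeneric("channelScale", function(x, role) standardGeneric("channelScale"))

#' @rdname gatingAccessors
#' @export
setGeneric("gateMask", function(x, stage) standardGeneric("gateMask"))

#' @rdname gatingAccessors
#' @export
setGeneric("gateCounts", function(x) standardGeneric("gateCounts"))

#' @rdname gatingAccessors
#' @export
setGeneric("heuristicsApplied", function(x) standardGeneric("heuristicsApplied"))

#' @rdname gatingAccessors
#' @export
setGeneric("viabilityCutoff", function(x) standardGeneric("viabilityCutoff"))

#' @rdname sputumClassifier
#' @export
setGeneric("modelCoefficients", function(object) standardGeneric("modelCoefficients"))

#' @rdname sputumClassifier
#' @export
setGeneric("modelCutoff", function(object) standardGeneric("modelCutoff"))
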