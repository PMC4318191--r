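#' @rdname echoTimes
#' @export
setGeneric("echoTimes", function(x) standardGeneric("echoTimes"))

#' @rdname nEchoes
#' @export
setGeneric("nEchoes", function(x) standardGeneric("nEchoes"))

#' @rdname t2Values
#' @export
setGeneric("t2Values", function(x) standardGeneric("t2Values"))

#' @rdname acceptedMask
#' @export
setGeneric("acceptedMask", function(x) standardGeneric("acceptedMask"))

#' @rdname acceptanceStats
#' @export
setGeneric("acceptanceStats", function(x) standardGeneric("acceptanceStats"))

#' @rdname segmentLabels
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname sliceLevel
#' @export
setGeneric("sliceLevel", function(x) standardGeneric("sliceLevel"))

#' @rdname strainValues
#' @export
setGeneric("strainValues", function(x) standardGeneric("strainValues"))

#' @rdname frameTimes
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
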