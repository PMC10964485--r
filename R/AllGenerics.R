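#' @import methods
NULL

#' @rdname redoxCalibration
#' @param object A `RedoxCalibration`.
#' @export
setGeneric("formalPotential", function(object) standardGeneric("formalPotential"))

#' @rdname redoxCalibration
#' @export
setGeneric("temperatureK", function(object) standardGeneric("temperatureK"))

#' @rdname redoxCalibration
#' @export
setGeneric("nernstSlope", function(object) standardGeneric("nernstSlope"))

#' @rdname bioreductionSeries
#' @param object A `BioreductionSeries`.
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' @rdname bioreductionSeries
#' @export
setGeneric("fe2", function(object) standardGeneric("fe2"))

#' @rdname bioreductionSeries
#' @export
setGeneric("feTotal", function(object) standardGeneric("feTotal"))

#' @rdname bioreductionSeries
#' @export
setGeneric("ehValues", function(object) standardGeneric("ehValues"))

#' @rdname bioreductionSeries
#' @export
setGeneric("cellCounts", function(object) standardGeneric("cellCounts"))

#' @rdname ironSpeciation
#' @param object An `IronSpeciation`.
#' @export
setGeneric("fe3", function(object) standardGeneric("fe3"))

#' @rdname ironSpeciation
#' @export
setGeneric("fe3Fraction", function(object) standardGeneric("fe3Fraction"))

#' @rdname maxRate
#' @param series A `BioreductionSeries`.
#' @param ... Further arguments passed to methods.
#' @export
setGeneric("maxRate", function(series, ...) standardGeneric("maxRate"))

#' @rdname meanRate
#' @param series A `BioreductionSeries`.
#' @param ... Further arguments passed to methods.
#' @export
setGeneric("meanRate", function(series, ...) standardGeneric("meanRate"))

#' @rdname rateLaw
#' @param object A `RateLaw`.
#' @export
setGeneric("rateSlope", function(object) standardGeneric("rateSlope"))

#' @rdname rateLaw
#' @export
setGeneric("rateIntercept", function(object) standardGeneric("rateIntercept"))

#' @rdname rateLaw
#' @export
setGeneric("rateR2", function(object) standardGeneric("rateR2"))

#' @rdname checkBalance
#' @param reaction A `Reaction`.
#' @export
setGeneric("checkBalance", function(reaction) standardGeneric("checkBalance"))

#' @rdname simulationResult
#' @param object A `SimulationResult`.
#' @export
setGeneric("stateTrajectories", function(object) standardGeneric("stateTrajectories"))

#' @rdname simulationResult
#' @export
setGeneric("steadyStateOf", function(object) standardGeneric("steadyStateOf"))

#' @rdname simulationResult
#' @export
setGeneric("diagnosticsOf", function(object) standardGeneric("diagnosticsOf"))
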