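#' @rdname CNVCallSet-class
#' @param x,object an object.
#' @export
setGeneric("callerName", function(x) standardGeneric("callerName"))

#' @rdname CNVCallSet-class
#' @export
setGeneric("cnvCalls", function(x) standardGeneric("cnvCalls"))

#' @rdname CNVCallSet-class
#' @export
setGeneric("nocallUnits", function(x) standardGeneric("nocallUnits"))

#' @rdname ValidationSet-class
#' @export
setGeneric("validatedCalls", function(x) standardGeneric("validatedCalls"))

#' @rdname ValidationSet-class
#' @export
setGeneric("validatedRegions",
           function(x) standardGeneric("validatedRegions"))

#' @rdname ValidationSet-class
#' @export
setGeneric("validationStates",
           function(x) standardGeneric("validationStates"))

#' @rdname OptimizationResult-class
#' @export
setGeneric("bestParams", function(x) standardGeneric("bestParams"))

#' @rdname OptimizationResult-class
#' @export
setGeneric("optimizationTable",
           function(x) standardGeneric("optimizationTable"))

#' @rdname CoverageExperiment-class
#' @export
setGeneric("droppedROIs", function(x) standardGeneric("droppedROIs"))

#' @rdname CoverageExperiment-class
#' @export
setGeneric("nocallSamples", function(x) standardGeneric("nocallSamples"))
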