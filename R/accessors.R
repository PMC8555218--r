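#' @rdname CNVCallSet-class
#' @export
setMethod("callerName", "CNVCallSet", function(x) x@callerName)

#' @rdname CNVCallSet-class
#' @export
setMethod("cnvCalls", "CNVCallSet", function(x) x@calls)

#' @rdname CNVCallSet-class
#' @export
setMethod("nocallUnits", "CNVCallSet", function(x) x@nocallUnits)

#' @rdname CNVCallSet-class
#' @export
setMethod("length", "CNVCallSet", function(x) length(x@calls))

#' @rdname ValidationSet-class
#' @export
setMethod("validatedCalls", "ValidationSet", function(x) x@validatedCalls)

#' @rdname ValidationSet-class
#' @export
setMethod("validatedRegions", "ValidationSet",
          function(x) x@validatedRegions)

#' @rdname ValidationSet-class
#' @export
setMethod("validationStates", "ValidationSet", function(x) x@states)

#' @rdname OptimizationResult-class
#' @export
setMethod("bestParams", "OptimizationResult", function(x) x@best)

#' @rdname OptimizationResult-class
#' @export
setMethod("optimizationTable", "OptimizationResult", function(x) x@table)

#' @rdname CoverageExperiment-class
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "CoverageExperiment",
          function(object) assay(object, "counts"))

#' @rdname CoverageExperiment-class
#' @export
setMethod("droppedROIs", "CoverageExperiment",
          function(x) metadata(x)$droppedROIs)

#' @rdname CoverageExperiment-class
#' @export
setMethod("nocallSamples", "CoverageExperiment",
          function(x) metadata(x)$nocallSamples)

#' @rdname CNVCallSet-class
#' @export
setMethod("show", "CNVCallSet", function(object) {
  cat(sprintf("CNVCallSet '%s': %d call(s) in %d sample(s); %d no-call unit(s)\n",
              object@callerName, length(object@calls),
              length(unique(mcols(object@calls)$sample)),
              nrow(object@nocallUnits)))
  if (length(object@calls)) {
    tab <- table(mcols(object@calls)$type)
    cat("  types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

#' @rdname CallerParams-class
#' @export
setMethod("show", "CallerParams", function(object) {
  cat(sprintf(
    "CallerParams: minCorrelation=%g, minCoverage=%g, transitionProb=%g\n",
    object@minCorrelation, object@minCoverage, object@transitionProb))
})

#' @rdname ValidationSet-class
#' @export
setMethod("show", "ValidationSet", function(object) {
  cat(sprintf(
    "ValidationSet: %d validated call(s) over %d region(s), %d sample(s)\n",
    length(object@validatedCalls), length(object@validatedRegions),
    nrow(object@states)))
  cat(sprintf("  overlap fraction %.2f, minimum size %.1f bp\n",
              object@overlapFraction, object@minSizeUsed))
})

#' @rdname ParameterGrid-class
#' @export
setMethod("show", "ParameterGrid", function(object) {
  cat(sprintf("ParameterGrid (%s): %d x %d x %d combinations\n",
              object@searchMode,
              length(object@correlationValues),
              length(object@coverageValues),
              length(object@transitionValues)))
})

#' @rdname OptimizationResult-class
#' @export
setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult: %d combination(s) evaluated, objective '%s'\n",
              nrow(object@table), object@objective))
  cat("  best: ")
  show(object@best)
})

#' @rdname BatchPlan-class
#' @export
setMethod("show", "BatchPlan", function(object) {
  cat(sprintf("BatchPlan with %d batch(es):\n", length(object@batches)))
  for (b in object@batches)
    cat(sprintf("  %s: %d sample(s), %d chromosome(s)%s\n", b$label,
                length(b$samples), length(b$chroms),
                if (isTRUE(b$unreliableSex)) " [sex chroms unreliable]" else ""))
})
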