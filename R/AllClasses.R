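#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width reduce
#'   findOverlaps pintersect
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment rowRanges colData
#'   assay assays
NULL

.SEX_CODES <- c("F", "M", "UNKNOWN")
.CNV_TYPES <- c("DEL", "DUP")

#' Tunable parameters of the read-depth caller
#'
#' Holds the three parameters exposed to optimization: the minimum Pearson
#' correlation for a cohort sample to enter a test sample's reference set,
#' the minimum median coverage for a sample or target region to be analysed,
#' and the probability of transitioning from the normal copy-number state
#' into a deletion or duplication state in the segmentation HMM.
#'
#' @slot minCorrelation numeric in (0,1); reference-selection threshold.
#' @slot minCoverage nonnegative numeric; median-coverage QC threshold
#'   (reads per target).
#' @slot transitionProb numeric in (0, 0.5); HMM normal-to-CNV transition
#'   probability. Lower values demand stronger per-event evidence.
#' @export
setClass("CallerParams",
  slots = c(minCorrelation = "numeric",
            minCoverage = "numeric",
            transitionProb = "numeric"))

setValidity("CallerParams", function(object) {
  msg <- character()
  for (s in c("minCorrelation", "minCoverage", "transitionProb")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg)) return(msg)
  if (object@minCorrelation <= 0 || object@minCorrelation >= 1)
    msg <- c(msg, "'minCorrelation' must lie in (0, 1)")
  if (object@minCoverage < 0)
    msg <- c(msg, "'minCoverage' must be nonnegative")
  if (object@transitionProb <= 0 || object@transitionProb >= 0.5)
    msg <- c(msg, "'transitionProb' must lie in (0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' @param minCorrelation,minCoverage,transitionProb see slot documentation.
#' @return A \code{CallerParams} object.
#' @examples
#' CallerParams()                      # defaults
#' CallerParams(transitionProb = 1e-4) # stricter segmentation
#' @rdname CallerParams-class
#' @export
CallerParams <- function(minCorrelation = 0.98, minCoverage = 100,
                         transitionProb = 0.01) {
  new("CallerParams", minCorrelation = minCorrelation,
      minCoverage = minCoverage, transitionProb = transitionProb)
}

#' A named set of CNV calls with abstention records
#'
#' One caller's output: deletion/duplication events as a \code{GRanges} with
#' metadata columns \code{type} (DEL or DUP), \code{sample}, and optionally
#' \code{readsRatio}, \code{copyNumber} and \code{unreliable}; plus the
#' (sample, ROI) units on which the caller abstained (no-calls) and why.
#'
#' @slot callerName single character identifying the caller.
#' @slot calls \code{GRanges}; within one sample, calls of the same type
#'   must not overlap.
#' @slot nocallUnits \code{data.frame} with columns \code{sample},
#'   \code{roi} (the ROI key) and \code{reason}.
#' @export
setClass("CNVCallSet",
  slots = c(callerName = "character",
            calls = "GRanges",
            nocallUnits = "data.frame"))

setValidity("CNVCallSet", function(object) {
  msg <- character()
  if (length(object@callerName) != 1L)
    msg <- c(msg, "'callerName' must be a single string")
  m <- mcols(object@calls)
  if (length(object@calls)) {
    if (!all(c("type", "sample") %in% colnames(m)))
      return("'calls' needs metadata columns 'type' and 'sample'")
    if (!all(m$type %in% .CNV_TYPES))
      msg <- c(msg, sprintf("unknown CNV type token(s): %s",
                            paste(setdiff(unique(m$type), .CNV_TYPES),
                                  collapse = ", ")))
    key <- paste(m$sample, m$type)
    disj <- IRanges::isDisjoint(S4Vectors::split(
      GenomicRanges::granges(object@calls), key))
    if (!all(disj))
      msg <- c(msg, sprintf(
        "overlapping same-type calls within sample/type '%s'",
        paste(names(disj)[!disj], collapse = "', '")))
  }
  if (!all(c("sample", "roi", "reason") %in% colnames(object@nocallUnits)))
    msg <- c(msg, "'nocallUnits' needs columns sample, roi, reason")
  if (length(msg)) msg else TRUE
})

#' @param callerName caller label.
#' @param calls \code{GRanges} of events (see slots).
#' @param nocallUnits abstention records; defaults to none.
#' @return A \code{CNVCallSet}.
#' @rdname CNVCallSet-class
#' @export
CNVCallSet <- function(callerName, calls = GRanges(),
                       nocallUnits = emptyNocallUnits()) {
  if (!length(calls) && !"type" %in% colnames(mcols(calls))) {
    mcols(calls)$type <- character()
    mcols(calls)$sample <- character()
  }
  if (length(calls) && is.null(mcols(calls)$readsRatio))
    mcols(calls)$readsRatio <- NA_real_
  if (length(calls) && is.null(mcols(calls)$copyNumber))
    mcols(calls)$copyNumber <- NA_integer_
  new("CNVCallSet", callerName = callerName, calls = calls,
      nocallUnits = nocallUnits)
}

emptyNocallUnits <- function() {
  data.frame(sample = character(), roi = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Per-target read counts for a cohort
#'
#' A \code{RangedSummarizedExperiment} whose rows are the capture targets
#' (ROIs, with metadata columns \code{name} and per-chromosome \code{index})
#' and whose columns are cohort samples (\code{colData} columns \code{sex}
#' in F/M/UNKNOWN and \code{family}, the relatedness group or NA). The single
#' assay \code{counts} holds nonnegative integer read counts. QC results
#' (dropped ROIs, no-call samples) are recorded in \code{metadata()}.
#'
#' @export
setClass("CoverageExperiment",
  contains = "RangedSummarizedExperiment")

setValidity("CoverageExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- assay(object, "counts")
  if (any(!is.finite(cnt)) || any(cnt < 0))
    msg <- c(msg, "counts must be finite and nonnegative")
  cd <- colData(object)
  if (!all(c("sex", "family") %in% colnames(cd)))
    msg <- c(msg, "colData needs columns 'sex' and 'family'")
  else if (!all(cd$sex %in% .SEX_CODES))
    msg <- c(msg, "sex codes must be F, M or UNKNOWN")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample names must be unique")
  if (length(msg)) msg else TRUE
})

#' @param counts ROI x sample matrix of nonnegative integers; rownames are
#'   ROI keys, colnames sample names.
#' @param rois \code{GRanges} of targets as returned by
#'   \code{\link{readTargetBed}}, parallel to the rows of \code{counts}.
#' @param samples \code{data.frame} with columns \code{sample}, \code{sex},
#'   \code{family} (see \code{\link{readSampleSheet}}).
#' @return A \code{CoverageExperiment}.
#' @rdname CoverageExperiment-class
#' @export
CoverageExperiment <- function(counts, rois, samples) {
  stopifnot(nrow(counts) == length(rois),
            ncol(counts) == nrow(samples))
  cd <- DataFrame(sex = samples$sex, family = samples$family,
                  row.names = samples$sample)
  colnames(counts) <- samples$sample
  rownames(counts) <- roiKey(rois)
  se <- SummarizedExperiment(assays = list(counts = counts),
                             rowRanges = rois, colData = cd)
  obj <- new("CoverageExperiment", se)
  metadata(obj)$droppedROIs <- data.frame(roi = character(),
                                          reason = character())
  metadata(obj)$nocallSamples <- data.frame(sample = character(),
                                            reason = character())
  obj
}

#' In silico validation set
#'
#' The consensus-validated CNVs, the merged genomic footprint they cover
#' (validated regions), and the full per-(sample, region) truth-state matrix
#' in which every sample without a validated CNV over a region is assigned
#' the normal copy-number state.
#'
#' @slot validatedCalls \code{GRanges} with \code{type} and \code{sample}.
#' @slot validatedRegions \code{GRanges}; disjoint union of call footprints.
#' @slot states character matrix, samples x regions, over
#'   DEL/NORMAL/DUP.
#' @slot minSizeUsed numeric; minimum consensus size applied (bp).
#' @slot overlapFraction numeric; reciprocal-free overlap fraction applied.
#' @export
setClass("ValidationSet",
  slots = c(validatedCalls = "GRanges",
            validatedRegions = "GRanges",
            states = "matrix",
            minSizeUsed = "numeric",
            overlapFraction = "numeric"))

setValidity("ValidationSet", function(object) {
  msg <- character()
  if (length(object@validatedRegions) &&
      !IRanges::isDisjoint(object@validatedRegions))
    msg <- c(msg, "validated regions must be disjoint")
  if (length(object@validatedRegions) != ncol(object@states))
    msg <- c(msg, "states must have one column per validated region")
  if (nrow(object@states) &&
      !all(object@states %in% c("DEL", "NORMAL", "DUP")))
    msg <- c(msg, "states must be DEL, NORMAL or DUP")
  if (length(msg)) msg else TRUE
})

#' Grid of caller parameter values to search
#'
#' @slot correlationValues,coverageValues,transitionValues sorted numeric
#'   vectors (at most 22 values each) that each contain the corresponding
#'   default of \code{\link{CallerParams}}.
#' @slot searchMode \code{"full_grid"} (evaluate every combination) or
#'   \code{"coordinate"} (per-parameter sweeps; a heuristic for large grids).
#' @export
setClass("ParameterGrid",
  slots = c(correlationValues = "numeric",
            coverageValues = "numeric",
            transitionValues = "numeric",
            searchMode = "character"))

setValidity("ParameterGrid", function(object) {
  msg <- character()
  def <- CallerParams()
  chk <- function(v, nm, lo, hi, defv) {
    out <- character()
    if (!length(v)) out <- c(out, sprintf("'%s' must be non-empty", nm))
    if (length(v) > 22L)
      out <- c(out, sprintf("'%s' has %d values; at most 22 are supported",
                            nm, length(v)))
    if (is.unsorted(v, strictly = TRUE))
      out <- c(out, sprintf("'%s' must be strictly increasing", nm))
    if (any(v <= lo) || any(v >= hi))
      out <- c(out, sprintf("'%s' values must lie in (%g, %g)", nm, lo, hi))
    if (!any(abs(v - defv) < 1e-12))
      out <- c(out, sprintf("'%s' must contain the default value %g",
                            nm, defv))
    out
  }
  msg <- c(msg,
           chk(object@correlationValues, "correlationValues", 0, 1,
               def@minCorrelation),
           chk(object@coverageValues, "coverageValues", -1e-9, Inf,
               def@minCoverage),
           chk(object@transitionValues, "transitionValues", 0, 0.5,
               def@transitionProb))
  if (!object@searchMode %in% c("full_grid", "coordinate"))
    msg <- c(msg, "searchMode must be 'full_grid' or 'coordinate'")
  if (length(msg)) msg else TRUE
})

#' @param correlationValues,coverageValues,transitionValues,searchMode see
#'   slot documentation.
#' @return A \code{ParameterGrid}.
#' @rdname ParameterGrid-class
#' @export
ParameterGrid <- function(correlationValues, coverageValues,
                          transitionValues, searchMode = "full_grid") {
  new("ParameterGrid",
      correlationValues = sort(correlationValues),
      coverageValues = sort(coverageValues),
      transitionValues = sort(transitionValues),
      searchMode = searchMode)
}

#' Outcome of a parameter grid search
#'
#' @slot best the selected \code{CallerParams}.
#' @slot table \code{data.frame} with one row per evaluated combination:
#'   the three parameter values, the confusion counts and the five metrics.
#' @slot objective name of the maximized metric (default sensitivity).
#' @export
setClass("OptimizationResult",
  slots = c(best = "CallerParams",
            table = "data.frame",
            objective = "character"))

#' Batching plan for cohort calling
#'
#' Each batch is a list with elements \code{label}, \code{samples}
#' (sample names), \code{chroms} (chromosome names) and
#' \code{unreliableSex} (flag sex-chromosome calls as unreliable). Every
#' (sample, chromosome) pair is covered by exactly one batch.
#'
#' @slot batches list of batch descriptors.
#' @export
setClass("BatchPlan", slots = c(batches = "list"))
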