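## In silico validation: CNVs concordantly called by independent callers
## are accepted as true, replacing wet-lab (MLPA/aCGH) confirmation for the
## purpose of parameter optimization.

#' Consensus-validated CNV calls
#'
#' Intersects the call sets of independent callers per (sample, type,
#' chromosome): within each connected overlap component, one call per
#' caller (the fragment with the largest overlap with the component,
#' leftmost on ties) contributes, and the mutual intersection is validated
#' when (1) it covers at least \code{overlapFraction} of at least one
#' contributing call and (2) it is at least \code{minSize} bp long (by
#' default the mean target size). Callers that report no CNV in any sample
#' are discarded first, so a two-caller consensus is the fallback; fewer
#' than two non-empty call sets is an error. Validated spans are the
#' intersections, clipped to the target footprint.
#'
#' @param callsets list of \code{\link{CNVCallSet}}s.
#' @param rois targets as \code{GRanges}.
#' @param overlapFraction required overlap fraction (default 0.60) with at
#'   least one contributing call.
#' @param minSize minimum validated size in bp, or \code{"auto"} for the
#'   mean target size.
#' @return \code{GRanges} of validated calls (metadata: type, sample),
#'   sorted deterministically.
#' @export
buildValidationCalls <- function(callsets, rois, overlapFraction = 0.60,
                                 minSize = "auto") {
  nonEmpty <- Filter(function(cs) length(cnvCalls(cs)) > 0L, callsets)
  if (length(nonEmpty) < length(callsets))
    message(length(callsets) - length(nonEmpty),
            " caller(s) reported no CNV in any sample and were discarded")
  if (length(nonEmpty) < 2L)
    stop("consensus needs at least two non-empty call sets")
  if (identical(minSize, "auto")) minSize <- meanROISize(rois)
  footprint <- reduce(rois)
  sets <- lapply(nonEmpty, cnvCalls)
  keyOf <- function(g) paste(mcols(g)$sample, mcols(g)$type,
                             as.character(seqnames(g)), sep = "\r")
  keys <- lapply(sets, keyOf)
  common <- Reduce(intersect, lapply(keys, unique))
  out <- list()
  for (k in common) {
    grs <- lapply(seq_along(sets),
                  function(i) sets[[i]][keys[[i]] == k])
    comp <- reduce(.bindGRanges(lapply(grs, GenomicRanges::granges)))
    for (j in seq_along(comp)) {
      region <- comp[j]
      chosen <- lapply(grs, function(g) {
        ol <- overlapLength(g, region)
        hit <- which(ol > 0L)
        if (!length(hit)) return(NULL)
        hit <- hit[order(-ol[hit], start(g)[hit])]
        g[hit[1L]]
      })
      if (any(vapply(chosen, is.null, logical(1)))) next
      istart <- max(vapply(chosen, start, integer(1)))
      iend <- min(vapply(chosen, end, integer(1)))
      if (iend < istart) next
      len <- iend - istart + 1L
      fracOK <- any(vapply(chosen,
                           function(g) len >= overlapFraction * width(g),
                           logical(1)))
      if (!fracOK || len < minSize) next
      parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      span <- GRanges(parts[3L], IRanges(istart, iend))
      clip <- suppressWarnings(GenomicRanges::intersect(span, footprint))
      if (!length(clip)) next
      val <- GRanges(parts[3L], IRanges(min(start(clip)), max(end(clip))))
      mcols(val)$type <- parts[2L]
      mcols(val)$sample <- parts[1L]
      out[[length(out) + 1L]] <- val
    }
  }
  if (!length(out)) {
    g <- GRanges(); mcols(g)$type <- character()
    mcols(g)$sample <- character()
    return(g)
  }
  .sortCalls(unique(.bindGRanges(out)))
}

#' Attach normal-state assignments to validated calls
#'
#' The union footprint of all validated calls defines the validated
#' regions (overlaps merged). Every cohort sample is then assigned a state
#' at every validated region: its validated call's type where one overlaps,
#' otherwise the normal copy-number state. The result is the full truth
#' table the optimizer scores against.
#'
#' @param validated validated calls from
#'   \code{\link{buildValidationCalls}}.
#' @param samples sample sheet \code{data.frame} (column \code{sample}).
#' @param rois targets as \code{GRanges}.
#' @param overlapFraction,minSizeUsed provenance values recorded on the
#'   result.
#' @return A \code{\link{ValidationSet}}.
#' @export
attachNormalStates <- function(validated, samples, rois,
                               overlapFraction = 0.60,
                               minSizeUsed = NA_real_) {
  if (is.na(minSizeUsed)) minSizeUsed <- meanROISize(rois)
  sampleNames <- if (is.data.frame(samples)) samples$sample else samples
  if (length(validated) == 0L) {
    warning("no validated calls: the validation set is empty and ",
            "parameter optimization is impossible")
    st <- matrix(character(), nrow = length(sampleNames), ncol = 0L,
                 dimnames = list(sampleNames, NULL))
    return(new("ValidationSet", validatedCalls = validated,
               validatedRegions = GRanges(), states = st,
               minSizeUsed = minSizeUsed,
               overlapFraction = overlapFraction))
  }
  regions <- reduce(validated)
  rk <- roiKey(regions)
  st <- matrix("NORMAL", nrow = length(sampleNames), ncol = length(regions),
               dimnames = list(sampleNames, rk))
  bestOL <- matrix(0L, nrow = length(sampleNames), ncol = length(regions),
                   dimnames = list(sampleNames, rk))
  hits <- findOverlaps(validated, regions)
  for (h in seq_along(hits)) {
    qi <- S4Vectors::queryHits(hits)[h]
    sj <- S4Vectors::subjectHits(hits)[h]
    s <- mcols(validated)$sample[qi]
    ol <- overlapLength(validated[qi], regions[sj])
    if (ol > bestOL[s, sj]) {
      bestOL[s, sj] <- ol
      st[s, sj] <- mcols(validated)$type[qi]
    }
  }
  new("ValidationSet", validatedCalls = validated,
      validatedRegions = regions, states = st,
      minSizeUsed = minSizeUsed, overlapFraction = overlapFraction)
}

#' One-step construction of the in silico validation set
#'
#' Convenience wrapper running \code{\link{buildValidationCalls}} followed
#' by \code{\link{attachNormalStates}}.
#'
#' @inheritParams buildValidationCalls
#' @inheritParams attachNormalStates
#' @return A \code{\link{ValidationSet}}.
#' @export
buildValidationSet <- function(callsets, samples, rois,
                               overlapFraction = 0.60, minSize = "auto") {
  if (identical(minSize, "auto")) minSize <- meanROISize(rois)
  validated <- buildValidationCalls(callsets, rois, overlapFraction,
                                    minSize)
  attachNormalStates(validated, samples, rois, overlapFraction, minSize)
}
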