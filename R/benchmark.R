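## Per-unit benchmarking: each evaluation unit is one (sample, region)
## pair -- regions are either the capture targets themselves or the merged
## validated regions -- and carries exactly one label per matrix.

#' Project CNV calls onto an evaluation universe
#'
#' Builds the per-(sample, region) state matrix for a call set: a unit is
#' DEL or DUP when a call of that type from that sample overlaps the
#' region, otherwise NORMAL. When disjoint calls of both types fall inside
#' one merged evaluation region, the type with the larger overlap labels
#' the unit; overlapping opposite-type calls are a call-set integrity
#' error. Units the caller abstained on become NOCALL,
#' which the policy then resolves: \code{"as_normal"} (default) counts them
#' among the negatives, mirroring a diagnostic setting where uncalled
#' regions would need orthogonal confirmation; \code{"excluded"} removes
#' them from the universe (NA cells). A region counts as abstained for a
#' sample when no call overlaps it and every target ROI inside it is a
#' no-call unit for that sample.
#'
#' @param callset a \code{\link{CNVCallSet}}.
#' @param samples character vector of sample names (matrix rows).
#' @param regions \code{GRanges} of evaluation regions (matrix columns).
#' @param nocallPolicy \code{"as_normal"} or \code{"excluded"}.
#' @param rois targets as \code{GRanges}; needed to map per-ROI no-call
#'   units onto regions (defaults to \code{regions}).
#' @return character matrix samples x regions over DEL/NORMAL/DUP (and NA
#'   under the excluded policy).
#' @export
statesFromCalls <- function(callset, samples, regions,
                            nocallPolicy = c("as_normal", "excluded"),
                            rois = regions) {
  nocallPolicy <- match.arg(nocallPolicy)
  rk <- roiKey(regions)
  st <- matrix("NORMAL", nrow = length(samples), ncol = length(regions),
               dimnames = list(samples, rk))
  calls <- cnvCalls(callset)
  calls <- calls[mcols(calls)$sample %in% samples]
  if (length(calls)) {
    hits <- suppressWarnings(findOverlaps(calls, regions))
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ol <- overlapLength(calls[qh], regions[sh])
    srcIdx <- matrix(0L, nrow = length(samples), ncol = length(regions),
                     dimnames = dimnames(st))
    bestOL <- srcIdx
    for (h in seq_along(qh)) {
      s <- mcols(calls)$sample[qh[h]]
      ty <- mcols(calls)$type[qh[h]]
      cur <- st[s, sh[h]]
      if (cur != "NORMAL" && cur != ty) {
        ## overlapping opposite-type calls violate the call-set contract;
        ## disjoint ones inside a merged region resolve by larger overlap
        if (overlapLength(calls[qh[h]], calls[srcIdx[s, sh[h]]]) > 0L)
          stop(sprintf(
            "sample '%s' has overlapping DEL and DUP calls at unit %s",
            s, rk[sh[h]]))
        if (ol[h] <= bestOL[s, sh[h]]) next
      }
      if (ol[h] > bestOL[s, sh[h]]) {
        st[s, sh[h]] <- ty
        srcIdx[s, sh[h]] <- qh[h]
        bestOL[s, sh[h]] <- ol[h]
      }
    }
  }
  nc <- nocallUnits(callset)
  nc <- nc[nc$sample %in% samples, , drop = FALSE]
  if (nrow(nc)) {
    roiKeys <- roiKey(rois)
    hits <- suppressWarnings(findOverlaps(rois, regions))
    roisPerRegion <- split(roiKeys[S4Vectors::queryHits(hits)],
                           factor(S4Vectors::subjectHits(hits),
                                  levels = seq_along(regions)))
    ncBySample <- split(nc$roi, nc$sample)
    for (s in names(ncBySample)) {
      abst <- vapply(roisPerRegion, function(kk)
        length(kk) > 0L && all(kk %in% ncBySample[[s]]), logical(1))
      abst <- abst & st[s, ] == "NORMAL"
      if (any(abst))
        st[s, abst] <- if (nocallPolicy == "as_normal") "NORMAL"
                       else NA_character_
    }
  }
  st
}

#' Per-unit confusion counts
#'
#' Compares a predicted state matrix with a truth matrix over an identical
#' universe. A unit with a non-normal truth state is a true positive when
#' the prediction matches exactly and otherwise a false negative (by
#' default a wrong-type call, DEL for DUP, is a missed CNV rather than an
#' additional false positive; set \code{wrongType = "fp_fn"} to count it in
#' both categories). A normal-truth unit is a true negative or a false
#' positive. NA predictions (excluded no-calls) leave the universe.
#'
#' @param predicted,truth character matrices with identical dimnames.
#' @param wrongType \code{"fn"} (default) or \code{"fp_fn"}.
#' @return list with elements tp, tn, fp, fn, total.
#' @export
confusionCNV <- function(predicted, truth, wrongType = c("fn", "fp_fn")) {
  wrongType <- match.arg(wrongType)
  if (!identical(dimnames(predicted), dimnames(truth))) {
    d <- c(setdiff(rownames(predicted), rownames(truth)),
           setdiff(rownames(truth), rownames(predicted)),
           setdiff(colnames(predicted), colnames(truth)),
           setdiff(colnames(truth), colnames(predicted)))
    stop("predicted and truth universes differ: ",
         paste(utils::head(unique(d), 10), collapse = ", "))
  }
  keep <- !is.na(predicted)
  p <- predicted[keep]; tr <- truth[keep]
  posT <- tr != "NORMAL"
  tp <- sum(posT & p == tr)
  wrong <- sum(posT & p != "NORMAL" & p != tr)
  fn <- sum(posT & p == "NORMAL") + wrong
  tn <- sum(!posT & p == "NORMAL")
  fp <- sum(!posT & p != "NORMAL") +
    if (wrongType == "fp_fn") wrong else 0L
  list(tp = tp, tn = tn, fp = fp, fn = fn, total = tp + tn + fp + fn)
}

#' Performance metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), positive and negative
#' predictive values TP/(TP+FP) and TN/(TN+FN), and the F-score (harmonic
#' mean of PPV and sensitivity). A metric with a zero denominator is NA.
#'
#' @param counts list with tp, tn, fp, fn (e.g. from
#'   \code{\link{confusionCNV}}).
#' @return named list of the five metrics (full precision).
#' @examples
#' m <- cnvMetrics(list(tp = 247, tn = 27330, fp = 60, fn = 49))
#' round(m$sensitivity, 4)  # 0.8345
#' @export
cnvMetrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  if (tp + tn + fp + fn == 0) stop("empty confusion table")
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- rat(tp, tp + fn)
  spec <- rat(tn, tn + fp)
  ppv <- rat(tp, tp + fp)
  npv <- rat(tn, tn + fn)
  f <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
    2 * ppv * sens / (ppv + sens) else NA_real_
  list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
       f_score = f)
}
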