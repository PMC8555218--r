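## The internal read-depth caller: reference selection by correlation,
## median-coverage QC, reads-ratio normalization, 3-state HMM segmentation
## and ratio -> copy-number mapping. Its three tunable parameters
## (minCorrelation, minCoverage, transitionProb) are the optimizer's
## search space.

#' Infer sample sexes from sex-chromosome coverage
#'
#' For samples recorded as UNKNOWN, compares mean chrX and chrY counts with
#' the sample's autosomal median: a sample is male when its mean chrY count
#' is at least 0.25x the autosomal median and its mean chrX count is at
#' most 0.75x; female when chrY falls below 0.25x. Ambiguous samples
#' (chrY present but chrX not depleted) resolve to female with a warning.
#' Samples with a recorded sex are passed through unchanged.
#'
#' @param cov a \code{\link{CoverageExperiment}}.
#' @return named character vector of sex codes (F/M) for every sample.
#' @export
inferSex <- function(cov) {
  sexes <- stats::setNames(colData(cov)$sex, colnames(cov))
  unk <- names(sexes)[sexes == "UNKNOWN"]
  if (!length(unk)) return(sexes)
  cls <- .chromClass(as.character(seqnames(rowRanges(cov))))
  if (!any(cls %in% c("X", "Y")))
    stop("cannot infer sex: target has no sex-chromosome ROIs; ",
         "provide explicit sexes in the sample sheet")
  cnt <- counts(cov)
  for (s in unk) {
    amed <- stats::median(cnt[cls == "autosome", s])
    my <- if (any(cls == "Y")) mean(cnt[cls == "Y", s]) else 0
    mx <- if (any(cls == "X")) mean(cnt[cls == "X", s]) else NA_real_
    if (my >= 0.25 * amed) {
      if (is.na(mx) || mx <= 0.75 * amed) {
        sexes[s] <- "M"
      } else {
        warning(sprintf(
          "ambiguous sex-chromosome coverage for sample '%s'; calling F", s))
        sexes[s] <- "F"
      }
    } else {
      sexes[s] <- "F"
    }
  }
  sexes
}

#' Plan calling batches by sex
#'
#' By default, calling is split into a female and a male batch over all
#' chromosomes, which keeps sex-chromosome baselines homogeneous; when
#' either sex has fewer than 5 samples, everything runs in one batch and
#' sex-chromosome calls are flagged unreliable. The \code{"batch2"} mode
#' keeps a single mixed batch for autosomes and splits only the sex
#' chromosomes by sex (requires 5+ of each sex). \code{"single"} forces one
#' batch.
#'
#' @param samples \code{data.frame} with columns sample, sex (resolved to
#'   F/M), family.
#' @param rois targets as \code{GRanges}.
#' @param mode one of \code{"default"}, \code{"batch2"}, \code{"single"}.
#' @return A \code{\link{BatchPlan}}.
#' @export
planBatches <- function(samples, rois,
                        mode = c("default", "batch2", "single")) {
  mode <- match.arg(mode)
  if (nrow(samples) == 0L) stop("no samples to batch")
  if (any(!samples$sex %in% c("F", "M")))
    stop("sexes must be resolved (F/M) before batching; run inferSex()")
  chroms <- orderChroms(unique(as.character(seqnames(rois))))
  sexChr <- chroms[isSexChrom(chroms)]
  autoChr <- setdiff(chroms, sexChr)
  fs <- samples$sample[samples$sex == "F"]
  ms <- samples$sample[samples$sex == "M"]
  single <- list(label = "all", samples = samples$sample, chroms = chroms,
                 unreliableSex = TRUE)
  batches <- switch(mode,
    single = list(single),
    default = {
      if (length(fs) >= 5L && length(ms) >= 5L)
        list(list(label = "F", samples = fs, chroms = chroms,
                  unreliableSex = FALSE),
             list(label = "M", samples = ms, chroms = chroms,
                  unreliableSex = FALSE))
      else list(single)
    },
    batch2 = {
      if (length(fs) < 5L || length(ms) < 5L) {
        warning("batch2 requires at least 5 samples of each sex; ",
                "falling back to a single batch")
        list(single)
      } else if (!length(sexChr)) {
        list(list(label = "mixed", samples = samples$sample,
                  chroms = chroms, unreliableSex = FALSE))
      } else {
        list(list(label = "autosomes", samples = samples$sample,
                  chroms = autoChr, unreliableSex = FALSE),
             list(label = "XY-F", samples = fs, chroms = sexChr,
                  unreliableSex = FALSE),
             list(label = "XY-M", samples = ms, chroms = sexChr,
                  unreliableSex = FALSE))
      }
    })
  new("BatchPlan", batches = batches)
}

#' Median-coverage QC filters
#'
#' Drops every ROI whose median count across samples falls below
#' \code{minCoverage}, and marks as no-call every sample whose median count
#' across the (pre-drop) ROIs falls below \code{minCoverage}. Both filters
#' can be toggled. Dropped ROIs and no-call samples are recorded with
#' reasons in the returned object's metadata; rows of dropped ROIs are
#' removed, no-call sample columns are retained (they are skipped as test
#' samples and excluded from references downstream).
#'
#' @param cov a \code{\link{CoverageExperiment}}.
#' @param params a \code{\link{CallerParams}}.
#' @param roiFilter,sampleFilter logical toggles.
#' @return a filtered \code{CoverageExperiment}.
#' @export
applyQCFilters <- function(cov, params = CallerParams(), roiFilter = TRUE,
                           sampleFilter = TRUE) {
  qc <- .qcMat(counts(cov), params@minCoverage, roiFilter, sampleFilter)
  dropped <- rbind(metadata(cov)$droppedROIs, qc$dropped)
  nocall <- rbind(metadata(cov)$nocallSamples, qc$nocall)
  cov <- cov[qc$keep, ]
  metadata(cov)$droppedROIs <- dropped
  metadata(cov)$nocallSamples <- nocall
  cov
}

## Row medians for a small fixed column count.
.rowMedians <- function(m) {
  k <- ncol(m)
  if (k == 1L) return(m[, 1L])
  s <- apply(m, 1L, sort.int, method = "quick")
  if (k %% 2L) s[(k + 1L) %/% 2L, ] else (s[k %/% 2L, ] + s[k %/% 2L + 1L, ]) / 2
}

.qcMat <- function(cnt, minCoverage, roiFilter, sampleFilter) {
  dropped <- data.frame(roi = character(), reason = character())
  nocall <- data.frame(sample = character(), reason = character())
  if (sampleFilter) {
    smed <- apply(cnt, 2L, stats::median)
    low <- smed < minCoverage
    if (any(low))
      nocall <- data.frame(
        sample = colnames(cnt)[low],
        reason = sprintf("median coverage %.1f below %g",
                         smed[low], minCoverage))
  }
  keep <- rep(TRUE, nrow(cnt))
  if (roiFilter) {
    rmed <- .rowMedians(cnt)
    lowr <- rmed < minCoverage
    if (all(lowr))
      stop("all ROIs fall below the median-coverage threshold; ",
           "the batch is unusable")
    if (any(lowr))
      dropped <- data.frame(
        roi = rownames(cnt)[lowr],
        reason = sprintf("median coverage %.1f below %g",
                         rmed[lowr], minCoverage))
    keep <- !lowr
  }
  list(keep = keep, dropped = dropped, nocall = nocall)
}

#' Select a reference set for one test sample
#'
#' Candidates are the batch samples minus the test sample and any sample in
#' the same relatedness group (a shared family CNV would otherwise be
#' normalized away). Candidates whose Pearson correlation of raw count
#' profiles over the active ROIs reaches \code{minCorrelation} are kept,
#' sorted by decreasing correlation and truncated to at most 10 reference
#' samples. If none pass, the test sample is a no-call for the batch.
#'
#' @param test test sample name.
#' @param cov filtered \code{\link{CoverageExperiment}}.
#' @param params a \code{\link{CallerParams}}.
#' @param batch sample names to draw candidates from (default all).
#' @param corMatrix optional precomputed sample correlation matrix.
#' @param correlationFilter toggle for the correlation threshold.
#' @return list with elements \code{reference} (character), \code{nocall}
#'   (logical) and \code{reason}.
#' @export
selectReference <- function(test, cov, params = CallerParams(),
                            batch = colnames(cov), corMatrix = NULL,
                            correlationFilter = TRUE) {
  fam <- stats::setNames(as.character(colData(cov)$family), colnames(cov))
  if (is.null(corMatrix))
    corMatrix <- suppressWarnings(
      stats::cor(counts(cov)[, unique(c(test, batch)), drop = FALSE]))
  .pickRef(test, batch, fam, corMatrix, params, correlationFilter)
}

.pickRef <- function(test, batch, fam, corMatrix, params,
                     correlationFilter) {
  cand <- setdiff(batch, test)
  if (!is.na(fam[test]))
    cand <- cand[is.na(fam[cand]) | fam[cand] != fam[test]]
  if (!length(cand))
    return(list(reference = character(),
                nocall = TRUE, reason = "no reference candidates"))
  corr <- corMatrix[test, cand]
  corr[is.na(corr)] <- -1
  if (correlationFilter) {
    keep <- corr >= params@minCorrelation
    if (!any(keep))
      return(list(reference = character(), nocall = TRUE,
                  reason = sprintf("no candidate reaches correlation %g",
                                   params@minCorrelation)))
    cand <- cand[keep]; corr <- corr[keep]
  }
  o <- order(-corr, cand)
  list(reference = utils::head(cand[o], 10L), nocall = FALSE, reason = "")
}

#' Reads ratios and per-ROI emission SDs for a test sample
#'
#' Library-size-normalizes the counts (per-sample totals over active ROIs)
#' and divides the test sample's normalized profile by the median
#' normalized reference profile per ROI. The emission SD at each ROI is the
#' standard deviation of the reference samples' own normalized ratios at
#' that ROI, floored at 0.05. ROIs with zero reference median become
#' no-calls for this sample.
#'
#' @param test test sample name.
#' @param reference reference sample names.
#' @param cov filtered \code{\link{CoverageExperiment}}.
#' @return list with \code{ratio} and \code{sd} (named by ROI key, NA at
#'   no-call ROIs), \code{nocallROIs} and \code{nocallSample}.
#' @export
computeRatios <- function(test, reference, cov) {
  .ratiosMat(counts(cov), test, reference)
}

.ratiosMat <- function(cnt, test, reference) {
  stopifnot(length(reference) > 0L)
  cnt <- cnt[, c(test, reference), drop = FALSE]
  tot <- colSums(cnt)
  if (tot[test] == 0)
    return(list(ratio = NULL, sd = NULL, nocallROIs = character(),
                nocallSample = TRUE))
  norm <- sweep(cnt, 2L, tot, "/")
  refn <- norm[, reference, drop = FALSE]
  refmed <- .rowMedians(refn)
  bad <- refmed == 0
  ratio <- norm[, test] / refmed
  ratio[bad] <- NA_real_
  refratio <- refn / refmed
  k <- ncol(refratio)
  if (k > 1L) {
    rmean <- rowMeans(refratio)
    sdv <- sqrt(pmax(rowSums((refratio - rmean)^2), 0) / (k - 1L))
  } else sdv <- rep(NA_real_, nrow(refratio))
  sdv <- pmax(ifelse(is.finite(sdv), sdv, 0.05), 0.05)
  sdv[bad] <- NA_real_
  list(ratio = ratio, sd = sdv, nocallROIs = rownames(cnt)[bad],
       nocallSample = FALSE)
}

#' Viterbi segmentation of a reads-ratio vector
#'
#' Three-state hidden Markov model on the ratio scale with state means 0.5
#' (DEL), 1.0 (NORMAL) and 1.5 (DUP) and Gaussian emissions using the
#' per-ROI SDs. The normal state transitions into each CNV state with
#' probability \code{transitionProb}; CNV states return to normal with the
#' dwell parameter \code{exitProb} (default 1/3, i.e. an expected event
#' length of 3 ROIs) and cross directly between DEL and DUP with
#' probability \code{crossProb}. The initial distribution is
#' (t, 1 - 2t, t). The most likely path is computed per chromosome.
#'
#' @param ratios finite reads ratios, ordered along one chromosome.
#' @param params a \code{\link{CallerParams}}.
#' @param sd positive per-ROI emission SDs, parallel to \code{ratios}.
#' @param exitProb CNV-to-normal transition probability.
#' @param crossProb direct DEL-to-DUP (and back) transition probability.
#' @return character vector of states over DEL/NORMAL/DUP.
#' @export
viterbiSegment <- function(ratios, params = CallerParams(), sd,
                           exitProb = 1/3, crossProb = 1e-6) {
  L <- length(ratios)
  stateNames <- c("DEL", "NORMAL", "DUP")
  if (L == 0L) return(character())
  stopifnot(all(is.finite(ratios)), length(sd) == L, all(sd > 0))
  t <- params@transitionProb
  ## log-transitions; state order DEL, NORMAL, DUP
  aDD <- log(1 - exitProb - crossProb); aDN <- log(exitProb)
  aDU <- log(crossProb)
  aND <- log(t); aNN <- log(1 - 2 * t); aNU <- aND
  aUD <- aDU; aUN <- aDN; aUU <- aDD
  emD <- stats::dnorm(ratios, 0.5, sd, log = TRUE)
  emN <- stats::dnorm(ratios, 1.0, sd, log = TRUE)
  emU <- stats::dnorm(ratios, 1.5, sd, log = TRUE)
  d1 <- aND + emD[1L]; d2 <- aNN + emN[1L]; d3 <- aND + emU[1L]
  p1 <- integer(L); p2 <- integer(L); p3 <- integer(L)
  if (L > 1L) for (i in 2:L) {
    cA <- d1 + aDD; cB <- d2 + aND; cC <- d3 + aUD
    if (cA >= cB && cA >= cC) { n1 <- cA; p1[i] <- 1L }
    else if (cB >= cC) { n1 <- cB; p1[i] <- 2L }
    else { n1 <- cC; p1[i] <- 3L }
    cA <- d1 + aDN; cB <- d2 + aNN; cC <- d3 + aUN
    if (cA >= cB && cA >= cC) { n2 <- cA; p2[i] <- 1L }
    else if (cB >= cC) { n2 <- cB; p2[i] <- 2L }
    else { n2 <- cC; p2[i] <- 3L }
    cA <- d1 + aDU; cB <- d2 + aNU; cC <- d3 + aUU
    if (cA >= cB && cA >= cC) { n3 <- cA; p3[i] <- 1L }
    else if (cB >= cC) { n3 <- cB; p3[i] <- 2L }
    else { n3 <- cC; p3[i] <- 3L }
    d1 <- n1 + emD[i]; d2 <- n2 + emN[i]; d3 <- n3 + emU[i]
  }
  path <- integer(L)
  path[L] <- which.max(c(d1, d2, d3))
  if (L > 1L) for (i in (L - 1L):1L)
    path[i] <- switch(path[i + 1L], p1[i + 1L], p2[i + 1L], p3[i + 1L])
  stateNames[path]
}

#' Map a reads ratio to an integer copy number
#'
#' Banded mapping on a diploid background: ratios at or below 0.1 are CN0,
#' up to 0.8 CN1, up to 1.2 CN2, up to 1.8 CN3, up to 2.2 CN4; above 2.2
#' the copy number is twice the ratio, rounded half-up.
#'
#' @param readsRatio nonnegative ratio(s).
#' @return integer copy number(s).
#' @examples
#' mapRatioToCN(c(0.1, 1.5, 2.5))  # 0 3 5
#' @export
mapRatioToCN <- function(readsRatio) {
  if (any(!is.finite(readsRatio)) || any(readsRatio < 0))
    stop("reads ratio must be finite and nonnegative")
  ifelse(readsRatio <= 0.1, 0L,
  ifelse(readsRatio <= 0.8, 1L,
  ifelse(readsRatio <= 1.2, 2L,
  ifelse(readsRatio <= 1.8, 3L,
  ifelse(readsRatio <= 2.2, 4L,
         as.integer(floor(readsRatio * 2 + 0.5)))))))
}

#' Collapse per-ROI states into CNV calls
#'
#' Maximal runs of consecutive ROIs sharing a non-normal state on one
#' chromosome become a single call spanning the first ROI's start to the
#' last ROI's end; the call's reads ratio is the mean over the run and its
#' copy number follows \code{\link{mapRatioToCN}}.
#'
#' @param states per-ROI states (DEL/NORMAL/DUP).
#' @param rois \code{GRanges} parallel to \code{states}.
#' @param ratios reads ratios parallel to \code{states}.
#' @param sample sample name for the emitted calls.
#' @return \code{GRanges} of calls.
#' @export
mergeCalls <- function(states, rois, ratios, sample) {
  stopifnot(length(states) == length(rois), length(ratios) == length(rois))
  if (!length(states)) return(.emptyCalls())
  chrom <- as.character(seqnames(rois))
  r <- rle(paste(chrom, states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(states[starts] != "NORMAL")
  if (!length(keep)) return(.emptyCalls())
  i0 <- starts[keep]; i1 <- ends[keep]
  mr <- vapply(seq_along(keep),
               function(k) mean(ratios[i0[k]:i1[k]]), numeric(1))
  gr <- GRanges(chrom[i0], IRanges(start(rois)[i0], end(rois)[i1]))
  mcols(gr)$type <- states[i0]
  mcols(gr)$sample <- sample
  mcols(gr)$readsRatio <- mr
  mcols(gr)$copyNumber <- mapRatioToCN(mr)
  gr
}

.emptyCalls <- function() {
  gr <- GRanges()
  mcols(gr)$type <- character()
  mcols(gr)$sample <- character()
  mcols(gr)$readsRatio <- numeric()
  mcols(gr)$copyNumber <- integer()
  gr
}

#' Call CNVs across a cohort
#'
#' Runs the full caller: sex resolution (inferring UNKNOWN sexes from
#' coverage), batch planning, median-coverage QC, per-sample reference
#' selection, reads-ratio computation, per-chromosome Viterbi segmentation
#' and call merging. No-call units (dropped ROIs, filtered samples,
#' zero-reference ROIs) are recorded with reasons. A failing batch is
#' isolated: its units become no-calls and the other batches proceed.
#'
#' @param cov a \code{\link{CoverageExperiment}}.
#' @param params a \code{\link{CallerParams}}.
#' @param mode batch mode, see \code{\link{planBatches}}.
#' @param roiFilter,sampleFilter,correlationFilter QC toggles.
#' @return A \code{\link{CNVCallSet}} (caller name \code{"depthCNV"});
#'   sex-chromosome calls from mixed batches carry
#'   \code{mcols()$unreliable == TRUE}.
#' @export
callCohort <- function(cov, params = CallerParams(),
                       mode = c("default", "batch2", "single"),
                       roiFilter = TRUE, sampleFilter = TRUE,
                       correlationFilter = TRUE) {
  mode <- match.arg(mode)
  prep <- .prepCohort(cov, params, mode, roiFilter, sampleFilter,
                      correlationFilter)
  .segmentCohort(prep, params)
}

## Phase 1: everything independent of the HMM transition probability --
## sex resolution, batching, QC, reference selection and reads ratios.
## The optimizer prepares once per (correlation, coverage) pair and
## sweeps transition values over the cheap phase 2.
.prepCohort <- function(cov, params, mode, roiFilter, sampleFilter,
                        correlationFilter) {
  sexes <- inferSex(cov)
  samples <- data.frame(sample = colnames(cov), sex = unname(sexes),
                        family = as.character(colData(cov)$family))
  plan <- planBatches(samples, rowRanges(cov), mode)
  cntAll <- counts(cov)
  grAll <- rowRanges(cov)
  chromAll <- as.character(seqnames(grAll))
  startAll <- start(grAll)
  endAll <- end(grAll)
  keysAll <- rownames(cntAll)
  fam <- stats::setNames(samples$family, samples$sample)
  batchPreps <- list()
  ncList <- list()
  for (b in plan@batches) {
    mask <- chromAll %in% b$chroms
    res <- tryCatch(
      .prepBatch(cntAll[mask, b$samples, drop = FALSE], chromAll[mask],
                 startAll[mask], endAll[mask], keysAll[mask], fam, params,
                 b, roiFilter, sampleFilter, correlationFilter),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("batch '%s' failed (%s); its units become no-calls",
                      b$label, conditionMessage(res)))
      ncList[[length(ncList) + 1L]] <- data.frame(
        sample = rep(b$samples, each = sum(mask)),
        roi = rep(keysAll[mask], times = length(b$samples)),
        reason = paste0("batch failure: ", conditionMessage(res)))
      next
    }
    batchPreps[[length(batchPreps) + 1L]] <- res
    if (nrow(res$nocall)) ncList[[length(ncList) + 1L]] <- res$nocall
  }
  list(batchPreps = batchPreps, ncList = ncList)
}

## Phase 2: Viterbi segmentation and call merging under the given
## transition probability.
.segmentCohort <- function(prep, params) {
  callRows <- list()
  for (bp in prep$batchPreps) {
    for (sp in bp$perSample) {
      ok <- !is.na(sp$ratio)
      for (ci in bp$chromIdx) {
        sel <- ci[ok[ci]]
        if (!length(sel)) next
        st <- viterbiSegment(sp$ratio[sel], params, sp$sd[sel])
        df <- .mergeRuns(st, bp$chrom[sel], bp$starts[sel], bp$ends[sel],
                         sp$ratio[sel], sp$sample)
        if (nrow(df)) {
          df$unreliable <- bp$unreliableSex & isSexChrom(df$chrom)
          callRows[[length(callRows) + 1L]] <- df
        }
      }
    }
  }
  calls <- if (length(callRows)) {
    df <- do.call(rbind, callRows)
    gr <- GRanges(df$chrom, IRanges(df$start, df$end))
    mcols(gr)$type <- df$type
    mcols(gr)$sample <- df$sample
    mcols(gr)$readsRatio <- df$readsRatio
    mcols(gr)$copyNumber <- df$copyNumber
    mcols(gr)$unreliable <- df$unreliable
    gr
  } else .emptyCalls()
  nocall <- if (length(prep$ncList))
    unique(do.call(rbind, prep$ncList)) else emptyNocallUnits()
  rownames(nocall) <- NULL
  CNVCallSet("depthCNV", .sortCalls(calls), nocall)
}

## Matrix-level batch preparation; plain data structures only, so no S4
## object is built inside the optimizer's hot loop.
.prepBatch <- function(cnt, chrom, starts, ends, keys, fam, params, batch,
                       roiFilter, sampleFilter, correlationFilter) {
  nc <- list()
  addNC <- function(sample, roi, reason) {
    if (length(roi))
      nc[[length(nc) + 1L]] <<- data.frame(sample = sample, roi = roi,
                                           reason = reason)
  }
  qc <- .qcMat(cnt, params@minCoverage, roiFilter, sampleFilter)
  if (nrow(qc$dropped))
    addNC(rep(batch$samples, each = nrow(qc$dropped)),
          rep(qc$dropped$roi, times = length(batch$samples)),
          "ROI dropped: low median coverage")
  ncs <- qc$nocall$sample
  for (s in ncs) addNC(s, keys, "sample below coverage threshold")
  active <- setdiff(batch$samples, ncs)
  cntA <- cnt[qc$keep, , drop = FALSE]
  chromA <- chrom[qc$keep]
  chromIdx <- split(seq_along(chromA), factor(chromA, unique(chromA)))
  corM <- if (length(active) > 1L)
    suppressWarnings(stats::cor(cntA[, active, drop = FALSE])) else NULL
  tot <- colSums(cntA[, active, drop = FALSE])
  normA <- sweep(cntA[, active, drop = FALSE], 2L, tot, "/")
  refCache <- new.env(parent = emptyenv())
  refStats <- function(reference) {
    key <- paste(reference, collapse = ",")
    if (is.null(refCache[[key]])) {
      refn <- normA[, reference, drop = FALSE]
      refmed <- .rowMedians(refn)
      bad <- refmed == 0
      k <- length(reference)
      sdv <- if (k > 1L) {
        refratio <- refn / refmed
        rmean <- rowMeans(refratio)
        sqrt(pmax(rowSums((refratio - rmean)^2), 0) / (k - 1L))
      } else rep(NA_real_, nrow(refn))
      sdv <- pmax(ifelse(is.finite(sdv), sdv, 0.05), 0.05)
      sdv[bad] <- NA_real_
      refCache[[key]] <- list(refmed = refmed, sdv = sdv, bad = bad)
    }
    refCache[[key]]
  }
  perSample <- list()
  for (s in active) {
    ref <- .pickRef(s, active, fam, corM, params, correlationFilter)
    if (ref$nocall) {
      addNC(s, keys, ref$reason)
      next
    }
    if (tot[s] == 0) {
      addNC(s, keys, "zero total count")
      next
    }
    rs <- refStats(ref$reference)
    addNC(s, rownames(cntA)[rs$bad], "zero reference median")
    perSample[[length(perSample) + 1L]] <- list(
      sample = s,
      ratio = ifelse(rs$bad, NA_real_, normA[, s] / rs$refmed),
      sd = rs$sdv)
  }
  nocall <- if (length(nc)) do.call(rbind, nc) else emptyNocallUnits()
  list(perSample = perSample, chrom = chromA, starts = starts[qc$keep],
       ends = ends[qc$keep], chromIdx = chromIdx,
       unreliableSex = batch$unreliableSex, nocall = nocall)
}

## Run-length merge of per-ROI states into call rows (one chromosome).
.mergeRuns <- function(states, chrom, starts, ends, ratios, sample) {
  r <- rle(states)
  re <- cumsum(r$lengths)
  rs <- re - r$lengths + 1L
  keep <- which(r$values != "NORMAL")
  if (!length(keep))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), type = character(),
                      sample = character(), readsRatio = numeric(),
                      copyNumber = integer()))
  mr <- vapply(keep, function(k) mean(ratios[rs[k]:re[k]]), numeric(1))
  data.frame(chrom = chrom[rs[keep]], start = starts[rs[keep]],
             end = ends[re[keep]], type = r$values[keep], sample = sample,
             readsRatio = mr, copyNumber = mapRatioToCN(mr))
}
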