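## Grid search over the caller's three parameters against the in silico
## validation set, maximizing sensitivity (per-unit, over validated
## regions) with deterministic tie-breaking.

#' Default parameter grid
#'
#' 12 correlation thresholds spanning 0.80-0.99, 10 coverage thresholds
#' spanning 20-200 reads and 10 roughly log-spaced transition probabilities
#' spanning 1e-5 to 0.2; each axis contains the caller default (0.98, 100,
#' 0.01), so the selected optimum can never score below the defaults.
#'
#' @return A \code{\link{ParameterGrid}} in full-grid mode (1200
#'   combinations).
#' @export
defaultGrid <- function() {
  ParameterGrid(
    correlationValues = c(0.80, 0.82, 0.84, 0.86, 0.88, 0.90, 0.92, 0.94,
                          0.96, 0.97, 0.98, 0.99),
    coverageValues = seq(20, 200, by = 20),
    transitionValues = c(1e-5, 3e-5, 1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03,
                         0.1, 0.2),
    searchMode = "full_grid")
}

#' Score one parameter combination against the validation set
#'
#' Runs the cohort caller with the given parameters, projects its calls
#' onto the (samples x validated regions) universe and scores them against
#' the validation states.
#'
#' @param params a \code{\link{CallerParams}}.
#' @param cov a \code{\link{CoverageExperiment}}.
#' @param validation a \code{\link{ValidationSet}}.
#' @param mode batch mode, see \code{\link{planBatches}}.
#' @param nocallPolicy see \code{\link{statesFromCalls}}.
#' @return list with \code{counts} (confusion) and \code{metrics}. An
#'   all-no-call run scores sensitivity 0, it is not an error.
#' @export
evaluateParams <- function(params, cov, validation,
                           mode = c("default", "batch2", "single"),
                           nocallPolicy = "as_normal") {
  mode <- match.arg(mode)
  if (length(validatedRegions(validation)) == 0L)
    stop("empty validation set; build the consensus first")
  calls <- suppressWarnings(callCohort(cov, params, mode))
  .scoreCallset(calls, cov, validation, nocallPolicy)
}

.scoreCallset <- function(calls, cov, validation, nocallPolicy) {
  pred <- statesFromCalls(calls, rownames(validationStates(validation)),
                          validatedRegions(validation),
                          nocallPolicy = nocallPolicy,
                          rois = rowRanges(cov))
  counts <- confusionCNV(pred, validationStates(validation))
  list(counts = counts, metrics = cnvMetrics(counts))
}

.evalRow <- function(params, cov, validation, mode, nocallPolicy) {
  ev <- evaluateParams(params, cov, validation, mode, nocallPolicy)
  data.frame(minCorrelation = params@minCorrelation,
             minCoverage = params@minCoverage,
             transitionProb = params@transitionProb,
             tp = ev$counts$tp, tn = ev$counts$tn,
             fp = ev$counts$fp, fn = ev$counts$fn,
             sensitivity = ev$metrics$sensitivity,
             specificity = ev$metrics$specificity,
             ppv = ev$metrics$ppv, npv = ev$metrics$npv,
             f_score = ev$metrics$f_score)
}

## Deterministic selection: maximize the objective; ties fall to higher
## F-score, then higher specificity, then the combination closest to the
## defaults in grid-rank space, then first in grid order.
.selectBest <- function(table, grid, objective) {
  obj <- table[[objective]]
  obj[is.na(obj)] <- -Inf
  f <- table$f_score; f[is.na(f)] <- -Inf
  sp <- table$specificity; sp[is.na(sp)] <- -Inf
  def <- CallerParams()
  rankDist <- function(vals, axis, defv) {
    (match(vals, axis) - match(defv, axis))^2
  }
  d2 <- rankDist(table$minCorrelation, grid@correlationValues,
                 def@minCorrelation) +
        rankDist(table$minCoverage, grid@coverageValues,
                 def@minCoverage) +
        rankDist(table$transitionProb, grid@transitionValues,
                 def@transitionProb)
  o <- order(-obj, -f, -sp, d2,
             match(table$minCorrelation, grid@correlationValues),
             match(table$minCoverage, grid@coverageValues),
             match(table$transitionProb, grid@transitionValues))
  o[1L]
}

#' Optimize the caller parameters
#'
#' Evaluates parameter combinations against the validation set and selects
#' the one maximizing the objective (default: sensitivity). Full-grid mode
#' evaluates every combination; coordinate mode sweeps one parameter at a
#' time holding the others at the current best, with a second pass if the
#' first changed anything (a heuristic for large grids). Ties are broken
#' toward higher F-score (preventing degenerate call-everything optima),
#' then higher specificity, then proximity to the defaults.
#'
#' @param cov a \code{\link{CoverageExperiment}}.
#' @param validation a \code{\link{ValidationSet}}.
#' @param grid a \code{\link{ParameterGrid}}.
#' @param objective metric to maximize.
#' @param mode batch mode.
#' @param nocallPolicy see \code{\link{statesFromCalls}}.
#' @return An \code{\link{OptimizationResult}}.
#' @export
optimizeParams <- function(cov, validation, grid = defaultGrid(),
                           objective = c("sensitivity", "f_score",
                                         "specificity", "ppv", "npv"),
                           mode = c("default", "batch2", "single"),
                           nocallPolicy = "as_normal") {
  objective <- match.arg(objective)
  mode <- match.arg(mode)
  if (length(validatedRegions(validation)) == 0L)
    stop("empty validation set; run the consensus step first")
  evalMemo <- new.env(parent = emptyenv())
  evalOne <- function(co, cv, tr) {
    key <- paste(co, cv, tr, sep = "_")
    if (is.null(evalMemo[[key]]))
      evalMemo[[key]] <- .evalRow(
        CallerParams(co, cv, tr), cov, validation, mode, nocallPolicy)
    evalMemo[[key]]
  }
  if (grid@searchMode == "full_grid") {
    ## reference selection, QC and ratios do not depend on the
    ## transition probability: prepare once per (correlation, coverage)
    ## pair and sweep transitions over the segmentation phase only
    rows <- list()
    for (co in grid@correlationValues) {
      for (cvv in grid@coverageValues) {
        prep <- suppressWarnings(.prepCohort(
          cov, CallerParams(co, cvv, 0.01), mode,
          roiFilter = TRUE, sampleFilter = TRUE,
          correlationFilter = TRUE))
        for (tr in grid@transitionValues) {
          calls <- .segmentCohort(prep, CallerParams(co, cvv, tr))
          ev <- .scoreCallset(calls, cov, validation, nocallPolicy)
          rows[[length(rows) + 1L]] <- data.frame(
            minCorrelation = co, minCoverage = cvv, transitionProb = tr,
            tp = ev$counts$tp, tn = ev$counts$tn,
            fp = ev$counts$fp, fn = ev$counts$fn,
            sensitivity = ev$metrics$sensitivity,
            specificity = ev$metrics$specificity,
            ppv = ev$metrics$ppv, npv = ev$metrics$npv,
            f_score = ev$metrics$f_score)
        }
      }
    }
    table <- do.call(rbind, rows)
  } else {
    cur <- c(co = CallerParams()@minCorrelation,
             cv = CallerParams()@minCoverage,
             tr = CallerParams()@transitionProb)
    sweepAxis <- function(cur, axis, vals) {
      rows <- lapply(vals, function(v) {
        p <- cur; p[axis] <- v
        evalOne(p["co"], p["cv"], p["tr"])
      })
      tab <- do.call(rbind, rows)
      best <- .selectBest(tab, grid, objective)
      cur[axis] <- vals[best]
      cur
    }
    for (pass in 1:2) {
      prev <- cur
      cur <- sweepAxis(cur, "co", grid@correlationValues)
      cur <- sweepAxis(cur, "cv", grid@coverageValues)
      cur <- sweepAxis(cur, "tr", grid@transitionValues)
      if (identical(prev, cur)) break
    }
    table <- do.call(rbind, as.list(evalMemo))
    table <- table[order(table$minCorrelation, table$minCoverage,
                         table$transitionProb), ]
  }
  rownames(table) <- NULL
  i <- .selectBest(table, grid, objective)
  best <- CallerParams(table$minCorrelation[i], table$minCoverage[i],
                       table$transitionProb[i])
  new("OptimizationResult", best = best, table = table,
      objective = objective)
}
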