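# A small shared cohort keeps the grid evaluations cheap.
optFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulateCohort(simConfig(nSamples = 20, nRoisAutosomal = 120,
                                      nRoisX = 8, nRoisY = 4, seed = 42))
      surr <- makeSurrogates(sim, baseSeed = 4200)
      vs <- buildValidationSet(surr, sim$samples, sim$rois)
      cache <<- list(sim = sim, vs = vs)
    }
    cache
  }
})

test_that("the default grid contains the defaults and respects the 22-value cap", {
  g <- defaultGrid()
  expect_true(0.98 %in% g@correlationValues)
  expect_true(100 %in% g@coverageValues)
  expect_true(0.01 %in% g@transitionValues)
  expect_identical(length(g@correlationValues) *
                     length(g@coverageValues) *
                     length(g@transitionValues), 1200L)
  tooMany <- sort(unique(c(seq(0.50, 0.97, length.out = 22), 0.98)))
  expect_error(ParameterGrid(tooMany, c(100), c(0.01)), "22")
  ## grids must contain each parameter's default
  expect_error(ParameterGrid(c(0.90, 0.95), c(100), c(0.01)), "default")
})

test_that("a singleton grid returns the defaults and evaluation is deterministic", {
  fx <- optFixture()
  g <- ParameterGrid(0.98, 100, 0.01)
  opt <- optimizeParams(fx$sim$coverage, fx$vs, g)
  expect_equal(bestParams(opt)@minCorrelation, 0.98)
  expect_equal(bestParams(opt)@minCoverage, 100)
  expect_equal(bestParams(opt)@transitionProb, 0.01)
  expect_identical(nrow(optimizationTable(opt)), 1L)
  e1 <- evaluateParams(CallerParams(), fx$sim$coverage, fx$vs)
  e2 <- evaluateParams(CallerParams(), fx$sim$coverage, fx$vs)
  expect_identical(e1, e2)
})

test_that("the selected optimum never scores below the defaults", {
  fx <- optFixture()
  g <- ParameterGrid(c(0.95, 0.98), c(50, 100), c(1e-3, 0.01, 0.1))
  opt <- optimizeParams(fx$sim$coverage, fx$vs, g)
  tab <- optimizationTable(opt)
  def <- tab[tab$minCorrelation == 0.98 & tab$minCoverage == 100 &
               tab$transitionProb == 0.01, ]
  best <- bestParams(opt)
  bestRow <- tab[tab$minCorrelation == best@minCorrelation &
                   tab$minCoverage == best@minCoverage &
                   tab$transitionProb == best@transitionProb, ]
  expect_gte(bestRow$sensitivity, def$sensitivity)
  expect_identical(nrow(tab), 12L)
  ## the table invariant: no entry beats the selected combination
  expect_true(all(tab$sensitivity <= bestRow$sensitivity + 1e-12,
                  na.rm = TRUE))
})

test_that("full-grid selection is invariant to axis enumeration order", {
  fx <- optFixture()
  g1 <- ParameterGrid(c(0.95, 0.98), c(50, 100), c(0.01, 0.1))
  g2 <- ParameterGrid(c(0.98, 0.95), c(100, 50), c(0.1, 0.01))
  o1 <- optimizeParams(fx$sim$coverage, fx$vs, g1)
  o2 <- optimizeParams(fx$sim$coverage, fx$vs, g2)
  expect_equal(bestParams(o1)@minCorrelation,
               bestParams(o2)@minCorrelation)
  expect_equal(bestParams(o1)@minCoverage, bestParams(o2)@minCoverage)
  expect_equal(bestParams(o1)@transitionProb,
               bestParams(o2)@transitionProb)
})

test_that("coordinate search never beats the full grid", {
  fx <- optFixture()
  cg <- ParameterGrid(c(0.95, 0.98), c(50, 100), c(1e-3, 0.01, 0.1),
                      searchMode = "coordinate")
  fg <- ParameterGrid(c(0.95, 0.98), c(50, 100), c(1e-3, 0.01, 0.1))
  oc <- optimizeParams(fx$sim$coverage, fx$vs, cg)
  of <- optimizeParams(fx$sim$coverage, fx$vs, fg)
  bestSens <- function(o) {
    tab <- optimizationTable(o); b <- bestParams(o)
    tab$sensitivity[tab$minCorrelation == b@minCorrelation &
                      tab$minCoverage == b@minCoverage &
                      tab$transitionProb == b@transitionProb]
  }
  expect_lte(bestSens(oc), bestSens(of) + 1e-12)
})

test_that("an empty validation set refuses to optimize", {
  fx <- optFixture()
  empty <- suppressWarnings(attachNormalStates(
    cnvCalls(CNVCallSet("x")), fx$sim$samples, fx$sim$rois))
  expect_error(optimizeParams(fx$sim$coverage, empty), "consensus")
  expect_error(evaluateParams(CallerParams(), fx$sim$coverage, empty),
               "empty validation")
})

test_that("all-nocall parameter combinations score zero, not an error", {
  fx <- optFixture()
  strict <- CallerParams(minCorrelation = 0.999999, minCoverage = 100,
                         transitionProb = 0.01)
  ev <- evaluateParams(strict, fx$sim$coverage, fx$vs)
  expect_identical(ev$counts$tp, 0L)
  expect_identical(ev$metrics$sensitivity, 0)
})

test_that("the grid-search fast path agrees with direct evaluation", {
  fx <- optFixture()
  g <- ParameterGrid(c(0.95, 0.98), c(50, 100), c(1e-3, 0.01, 0.1))
  opt <- optimizeParams(fx$sim$coverage, fx$vs, g)
  tab <- optimizationTable(opt)
  for (i in seq_len(nrow(tab))) {
    ev <- evaluateParams(CallerParams(tab$minCorrelation[i],
                                      tab$minCoverage[i],
                                      tab$transitionProb[i]),
                         fx$sim$coverage, fx$vs)
    expect_identical(tab$tp[i], ev$counts$tp)
    expect_identical(tab$fn[i], ev$counts$fn)
    expect_identical(tab$fp[i], ev$counts$fp)
    expect_equal(tab$sensitivity[i], ev$metrics$sensitivity)
  }
})
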