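test_that("identical calls across three callers validate in full", {
  rois <- makeROIs(10, len = 100L, gap = 50L)
  css <- lapply(c("a", "b", "c"), function(nm)
    makeCallSet("chr1", 100, 500, "DEL", "S1", caller = nm))
  ## the call covers several 100 bp targets; footprint clipping applies
  val <- buildValidationCalls(css, rois, minSize = 100)
  expect_length(val, 1)
  expect_identical(mcols(val)$type, "DEL")
  expect_identical(mcols(val)$sample, "S1")
})

test_that("partial overlaps follow the 60%-of-one-caller and min-size rules", {
  ## brute-force interval oracle for the three-way intersection
  spans <- list(c(100, 500), c(300, 700), c(250, 550))
  inter <- c(max(vapply(spans, `[`, 0, 1)), min(vapply(spans, `[`, 0, 2)))
  len <- inter[2] - inter[1]
  expect_identical(inter, c(300, 500))
  fracs <- vapply(spans, function(s) len / (s[2] - s[1]), 0)
  expect_true(any(fracs >= 0.6))           # 66.7% of the third caller
  rois <- makeROIs(14, len = 50L, gap = 0L)  # footprint covers 0-700
  css <- lapply(seq_along(spans), function(i)
    makeCallSet("chr1", spans[[i]][1], spans[[i]][2], "DEL", "S1",
                caller = paste0("c", i)))
  val <- buildValidationCalls(css, rois, minSize = 200)
  expect_length(val, 1)
  expect_identical(start(val) - 1L, 300L)
  expect_identical(end(val), 500L)
  ## min size above the intersection length rejects it
  expect_length(buildValidationCalls(css, rois, minSize = 201), 0)
})

test_that("consensus stratifies by type and sample", {
  rois <- makeROIs(10, len = 100L, gap = 0L)
  a <- makeCallSet("chr1", 100, 500, "DEL", "S1", "a")
  b <- makeCallSet("chr1", 100, 500, "DEL", "S1", "b")
  cDup <- makeCallSet("chr1", 100, 500, "DUP", "S1", "c")
  cS2 <- makeCallSet("chr1", 100, 500, "DEL", "S2", "c")
  expect_length(buildValidationCalls(list(a, b, cDup), rois,
                                     minSize = 100), 0)
  expect_length(buildValidationCalls(list(a, b, cS2), rois,
                                     minSize = 100), 0)
})

test_that("empty call sets trigger the two-caller fallback or an error", {
  rois <- makeROIs(10, len = 100L, gap = 0L)
  a <- makeCallSet("chr1", 100, 500, "DEL", "S1", "a")
  b <- makeCallSet("chr1", 150, 500, "DEL", "S1", "b")
  empty <- CNVCallSet("c")
  expect_message(val <- buildValidationCalls(list(a, b, empty), rois,
                                             minSize = 100),
                 "discarded")
  expect_length(val, 1)
  expect_error(suppressMessages(
    buildValidationCalls(list(a, empty, empty), rois, minSize = 100)),
    "two non-empty")
})

test_that("normal states are attached over merged validated regions", {
  rois <- makeROIs(10, len = 100L, gap = 0L)
  samples <- data.frame(sample = c("S1", "S2", "S3"))
  val <- cnvCalls(makeCallSet("chr1", 100, 500, "DEL", "S1"))
  vs <- attachNormalStates(val, samples, rois)
  st <- validationStates(vs)
  expect_identical(dim(st), c(3L, 1L))
  expect_identical(unname(st[, 1]), c("DEL", "NORMAL", "NORMAL"))
  ## overlapping validated calls in different samples merge into one region
  val2 <- cnvCalls(makeCallSet("chr1", c(100, 300), c(500, 800),
                               c("DEL", "DUP"), c("S1", "S2")))
  vs2 <- attachNormalStates(val2, samples, rois)
  expect_length(validatedRegions(vs2), 1)
  ## union-merge oracle for the merged span
  expect_identical(start(validatedRegions(vs2)) - 1L, 100L)
  expect_identical(end(validatedRegions(vs2)), 800L)
  expect_identical(unname(validationStates(vs2)[, 1]),
                   c("DEL", "DUP", "NORMAL"))
  ## no validated calls: empty set with warning
  expect_warning(vs0 <- attachNormalStates(
    cnvCalls(CNVCallSet("x")), samples, rois), "empty")
  expect_identical(ncol(validationStates(vs0)), 0L)
})

test_that("consensus is order-invariant and anti-monotone in callers", {
  sim <- simulateCohort(simConfig(nSamples = 16, nRoisAutosomal = 80,
                                  nRoisX = 6, nRoisY = 3, seed = 21))
  surr <- makeSurrogates(sim, baseSeed = 500)
  vs1 <- buildValidationSet(surr, sim$samples, sim$rois)
  vs2 <- buildValidationSet(rev(surr), sim$samples, sim$rois)
  expect_identical(as.character(validatedCalls(vs1)),
                   as.character(validatedCalls(vs2)))
  expect_identical(validationStates(vs1), validationStates(vs2))
  ## a fourth non-empty caller can only shrink or preserve the set
  extra <- perturbCalls(sim$truth, callerErrorProfile(seed = 999),
                        sim$rois, sim$samples, "surrogate4")
  vs3 <- buildValidationSet(c(surr, list(extra)), sim$samples, sim$rois)
  v3 <- validatedCalls(vs3); v1 <- validatedCalls(vs1)
  expect_lte(length(v3), length(v1))
  for (i in seq_along(v3)) {
    m <- which(mcols(v1)$sample == mcols(v3)$sample[i] &
                 mcols(v1)$type == mcols(v3)$type[i])
    expect_true(any(overlapLength(rep(v3[i], length(m)), v1[m]) > 0))
  }
})

test_that("validated consensus contains no events absent from the truth", {
  for (seed in c(101, 202, 303)) {
    sim <- simulateCohort(simConfig(nSamples = 24, nRoisAutosomal = 300,
                                    nRoisX = 12, nRoisY = 6, seed = seed))
    surr <- makeSurrogates(sim, baseSeed = seed * 7)
    val <- buildValidationCalls(surr, sim$rois)
    ok <- validatedInTruth(val, sim$truth, sim$rois)
    expect_true(all(ok))
  }
})
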