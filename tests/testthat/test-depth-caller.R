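test_that("batch planning follows the sex-split rules", {
  rois <- makeROIs(12, chrom = c(rep("chr1", 8), rep("chrX", 3), "chrY"))
  mkSamples <- function(nF, nM)
    data.frame(sample = sprintf("S%02d", seq_len(nF + nM)),
               sex = rep(c("F", "M"), c(nF, nM)),
               family = NA_character_)
  plan <- planBatches(mkSamples(6, 6), rois)
  expect_length(plan@batches, 2)
  expect_false(any(vapply(plan@batches, `[[`, TRUE, "unreliableSex")))
  ## fewer than 5 of one sex: single mixed batch, sex chroms unreliable
  plan2 <- planBatches(mkSamples(3, 9), rois)
  expect_length(plan2@batches, 1)
  expect_true(plan2@batches[[1]]$unreliableSex)
  expect_setequal(plan2@batches[[1]]$samples, mkSamples(3, 9)$sample)
  ## batch2: mixed autosomes plus per-sex sex-chromosome batches
  plan3 <- planBatches(mkSamples(6, 6), rois, mode = "batch2")
  expect_length(plan3@batches, 3)
  labs <- vapply(plan3@batches, `[[`, "", "label")
  expect_setequal(labs, c("autosomes", "XY-F", "XY-M"))
  ## every (sample, chromosome) pair covered exactly once
  cover <- do.call(rbind, lapply(plan3@batches, function(b)
    expand.grid(sample = b$samples, chrom = b$chroms)))
  expect_identical(nrow(unique(cover)), nrow(cover))
  expect_identical(nrow(cover), 12L * 3L)
  none <- data.frame(sample = character(), sex = character(),
                     family = character())
  expect_error(planBatches(none, rois), "no samples")
})

test_that("QC filters drop by median coverage and match a brute-force oracle", {
  rois <- makeROIs(4)
  cnt <- matrix(150, 4, 3, dimnames = list(roiKey(rois), NULL))
  cnt[2, ] <- c(10, 12, 8)
  cov <- makeCov(cnt, rois)
  qc <- applyQCFilters(cov, CallerParams())
  expect_identical(droppedROIs(qc)$roi, roiKey(rois)[2])
  expect_identical(nrow(cov) - nrow(qc), 1L)
  ## sample retained at median 150
  expect_identical(nrow(nocallSamples(qc)), 0L)

  set.seed(23)
  rois2 <- makeROIs(50)
  cnt2 <- matrix(rpois(50 * 30, 120), 50, 30,
                 dimnames = list(roiKey(rois2), NULL))
  cov2 <- makeCov(cnt2, rois2)
  qc2 <- applyQCFilters(cov2, CallerParams())
  dropOracle <- character()
  for (r in seq_len(50))
    if (median(cnt2[r, ]) < 100)
      dropOracle <- c(dropOracle, roiKey(rois2)[r])
  ncOracle <- character()
  for (s in seq_len(30))
    if (median(cnt2[, s]) < 100) ncOracle <- c(ncOracle, colnames(cov2)[s])
  expect_setequal(droppedROIs(qc2)$roi, dropOracle)
  expect_setequal(nocallSamples(qc2)$sample, ncOracle)
  ## all dropped -> unusable batch
  expect_error(applyQCFilters(makeCov(cnt * 0, rois), CallerParams()),
               "unusable")
})

test_that("raising minCoverage only grows the dropped set", {
  set.seed(5)
  rois <- makeROIs(40)
  cnt <- matrix(rnbinom(40 * 12, size = 20, mu = 150), 40, 12,
                dimnames = list(roiKey(rois), NULL))
  cov <- makeCov(cnt, rois)
  prev <- character()
  for (mc in c(20, 60, 100, 140)) {
    dropped <- droppedROIs(applyQCFilters(cov, CallerParams(
      minCoverage = mc)))$roi
    expect_true(all(prev %in% dropped))
    prev <- dropped
  }
})

test_that("reference selection caps at 10, filters by correlation and excludes family", {
  rois <- makeROIs(30)
  base <- rpois(30, 200)
  cnt <- sapply(1:13, function(i) base + rpois(30, 5))
  dimnames(cnt) <- list(roiKey(rois), sprintf("S%02d", 1:13))
  cov <- makeCov(cnt, rois)
  sel <- selectReference("S01", cov, CallerParams(minCorrelation = 0.9))
  expect_false(sel$nocall)
  expect_length(sel$reference, 10)
  ## uncorrelated candidates fail the threshold
  cnt2 <- cbind(S01 = base, S02 = rev(base), S03 = sample(base))
  rownames(cnt2) <- roiKey(rois)
  cov2 <- makeCov(cnt2, rois)
  sel2 <- selectReference("S01", cov2, CallerParams())
  expect_true(sel2$nocall)
  expect_match(sel2$reason, "correlation")
  ## relatives are excluded regardless of correlation
  cov3 <- makeCov(cnt[, 1:4], rois,
                  family = c("FAM1", "FAM1", NA, NA))
  sel3 <- selectReference("S01", cov3, CallerParams(minCorrelation = 0.5))
  expect_false("S02" %in% sel3$reference)
  ## singleton batch -> distinct no-call reason
  sel4 <- selectReference("S01", cov3, CallerParams(), batch = "S01")
  expect_true(sel4$nocall)
  expect_match(sel4$reason, "no reference candidates")
})

test_that("raising minCorrelation only shrinks reference sets", {
  set.seed(9)
  rois <- makeROIs(60)
  e <- rlnorm(60, 0, 1)
  cnt <- sapply(1:12, function(i) rnbinom(60, size = 100, mu = 300 * e))
  dimnames(cnt) <- list(roiKey(rois), sprintf("S%02d", 1:12))
  cov <- makeCov(cnt, rois)
  for (s in colnames(cnt)) {
    prev <- NULL
    for (mc in c(0.5, 0.8, 0.95, 0.99)) {
      sel <- selectReference(s, cov, CallerParams(minCorrelation = mc))
      cur <- if (sel$nocall) character() else sel$reference
      if (!is.null(prev)) expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("reads ratios are 1 for identical profiles and track focal events", {
  rois <- makeROIs(20)
  cnt <- matrix(rep(rpois(20, 300), 6), 20, 6,
                dimnames = list(roiKey(rois), sprintf("S%02d", 1:6)))
  cov <- makeCov(cnt, rois)
  rr <- computeRatios("S01", sprintf("S%02d", 2:6), cov)
  expect_equal(unname(rr$ratio), rep(1, 20))
  ## a global halving cancels out after library-size normalization
  cnt2 <- cnt; cnt2[, 1] <- cnt[, 1] %/% 2L
  rr2 <- computeRatios("S01", sprintf("S%02d", 2:6),
                       makeCov(cnt2, rois))
  expect_equal(unname(rr2$ratio), rep(1, 20), tolerance = 0.02)
  ## zero reference median marks the ROI nocall
  cnt3 <- cnt; cnt3[5, 2:6] <- 0L
  rr3 <- computeRatios("S01", sprintf("S%02d", 2:6),
                       makeCov(cnt3, rois))
  expect_true(is.na(rr3$ratio[5]))
  expect_identical(rr3$nocallROIs, roiKey(rois)[5])
})

test_that("a focal heterozygous deletion halves the ratio at its ROIs", {
  ## well-covered targets so counting noise stays small relative to the
  ## +/-0.1 band around the expected ratios
  hits <- 0; tot <- 0
  for (seed in 1:20) {
    set.seed(seed)
    rois <- makeROIs(60)
    e <- rlnorm(60, 0, 0.3)
    cnt <- sapply(1:8, function(i) rnbinom(60, size = 2000, mu = 3000 * e))
    dimnames(cnt) <- list(roiKey(rois), sprintf("S%02d", 1:8))
    delIdx <- 10:12
    cnt[delIdx, 1] <- rnbinom(3, size = 2000, mu = 3000 * e[delIdx] * 0.5)
    cov <- makeCov(cnt, rois)
    rr <- computeRatios("S01", sprintf("S%02d", 2:8), cov)
    tot <- tot + 60
    hits <- hits + sum(abs(rr$ratio[delIdx] - 0.5) < 0.1) +
      sum(abs(rr$ratio[-delIdx] - 1.0) < 0.1)
  }
  expect_gt(hits / tot, 0.95)
})

test_that("state runs merge into calls with mean ratios and CN", {
  rois <- makeROIs(4)
  calls <- mergeCalls(c("NORMAL", "DEL", "DEL", "NORMAL"), rois,
                      c(1, 0.52, 0.48, 1), "S1")
  expect_length(calls, 1)
  expect_identical(start(calls), start(rois)[2])
  expect_identical(end(calls), end(rois)[3])
  expect_equal(mcols(calls)$readsRatio, 0.5)
  expect_identical(mcols(calls)$copyNumber, 1L)
  expect_length(mergeCalls(rep("NORMAL", 4), rois, rep(1, 4), "S1"), 0)
  ## a type change breaks the run into adjacent calls
  two <- mergeCalls(c("DEL", "DEL", "DUP", "DUP"), rois,
                    c(0.5, 0.5, 1.5, 1.5), "S1")
  expect_length(two, 2)
  expect_identical(mcols(two)$type, c("DEL", "DUP"))
  expect_identical(end(two)[1] < start(two)[2], TRUE)
})

test_that("ratio-to-CN bands match the published mapping and are monotone", {
  expect_identical(mapRatioToCN(1.5), 3L)
  expect_identical(mapRatioToCN(0.1), 0L)
  expect_identical(mapRatioToCN(2.5), 5L)
  expect_identical(mapRatioToCN(c(0, 0.8, 0.81, 1.2, 1.21, 1.8, 2.2, 2.21)),
                   c(0L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_identical(mapRatioToCN(3.26), 7L)  # half-up above the bands
  expect_error(mapRatioToCN(-0.1), "nonnegative")
  x <- seq(0, 5, by = 0.01)
  expect_true(all(diff(mapRatioToCN(x)) >= 0L))
})

test_that("sex inference recovers simulated sexes", {
  ## the mean-vs-median rule presumes comparable capture efficiency
  ## between sex-chromosome and autosomal targets
  wrong <- 0; n <- 0
  for (seed in 1:10) {
    sim <- simulateCohort(simConfig(nSamples = 12, nRoisAutosomal = 60,
                                    nRoisX = 8, nRoisY = 6,
                                    captureEfficiencySdlog = 0.3,
                                    seed = seed))
    cov <- sim$coverage
    SummarizedExperiment::colData(cov)$sex <- "UNKNOWN"
    inferred <- suppressWarnings(inferSex(cov))
    wrong <- wrong + sum(inferred != sim$samples$sex)
    n <- n + length(inferred)
  }
  expect_lte(wrong / n, 0.02)
  ## provided sexes pass through untouched
  sim <- simulateCohort(simConfig(nSamples = 8, nRoisAutosomal = 40,
                                  nRoisX = 5, nRoisY = 3, seed = 1))
  expect_identical(unname(inferSex(sim$coverage)), sim$samples$sex)
  ## no sex chromosomes in the target: inference must refuse
  rois <- makeROIs(10)
  cnt <- matrix(200, 10, 2, dimnames = list(roiKey(rois), NULL))
  cov2 <- makeCov(cnt, rois, sex = c("UNKNOWN", "F"))
  expect_error(inferSex(cov2), "no sex-chromosome")
})

test_that("cohort calling recovers strong embedded events and stays quiet on nulls", {
  recalled <- 0; total <- 0
  for (seed in 1:3) {
    sim <- simulateCohort(simConfig(nSamples = 30, nRoisAutosomal = 120,
                                    nRoisX = 10, nRoisY = 5,
                                    eventsPerSampleRate = 0.5,
                                    eventLengthGeometricP = 0.3,
                                    seed = 400 + seed))
    cs <- suppressWarnings(callCohort(sim$coverage))
    tg <- cnvCalls(sim$truth)
    got <- cnvCalls(cs)
    cnt <- counts(sim$coverage)
    roiGR <- rowRanges(sim$coverage)
    sexOf <- stats::setNames(sim$samples$sex, sim$samples$sample)
    ## eligible events: every ROI retained by the coverage filter and a
    ## ratio displacement above 3 emission SDs (SD proxied by the
    ## between-sample spread of median-normalized counts)
    for (i in seq_along(tg)) {
      s <- mcols(tg)$sample[i]
      peers <- sim$samples$sample[sim$samples$sex == sexOf[s]]
      hit <- which(overlapsAny(roiGR, tg[i]))
      sub <- cnt[hit, peers, drop = FALSE]
      if (any(apply(sub, 1, median) < 100)) next
      rel <- sweep(sub, 1, apply(sub, 1, median), "/")
      sdv <- pmax(apply(rel, 1, sd), 0.05)
      disp <- abs(mcols(tg)$readsRatio[i] - 1)
      if (mean(disp / sdv) <= 3) next
      total <- total + 1
      m <- which(mcols(got)$sample == s &
                   mcols(got)$type == mcols(tg)$type[i])
      if (any(overlapLength(rep(tg[i], length(m)), got[m]) > 0))
        recalled <- recalled + 1
    }
  }
  expect_gte(recalled / total, 0.8)
  ## a null cohort yields a per-unit FP rate at most 0.01
  sim0 <- simulateCohort(simConfig(nSamples = 20, nRoisAutosomal = 100,
                                   nRoisX = 8, nRoisY = 4,
                                   eventsPerSampleRate = 0,
                                   seed = 314))
  cs0 <- suppressWarnings(callCohort(sim0$coverage))
  st <- statesFromCalls(cs0, sim0$samples$sample, sim0$rois,
                        rois = sim0$rois)
  expect_lte(mean(st != "NORMAL"), 0.01)
})

test_that("cohort calling is deterministic", {
  sim <- simulateCohort(simConfig(nSamples = 16, nRoisAutosomal = 60,
                                  nRoisX = 6, nRoisY = 3, seed = 77))
  c1 <- suppressWarnings(callCohort(sim$coverage))
  c2 <- suppressWarnings(callCohort(sim$coverage))
  p1 <- tempfile(); p2 <- tempfile()
  writeCallsBed(c1, p1); writeCallsBed(c2, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_identical(nocallUnits(c1), nocallUnits(c2))
})
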