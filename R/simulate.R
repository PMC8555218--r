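## Synthetic cohorts: negative-binomially dispersed per-target read counts
## with embedded multi-ROI DEL/DUP events, plus surrogate caller outputs
## (truth + dropout, boundary jitter and false calls) so consensus and
## optimization are testable without sequencing data.

#' Simulation configuration
#'
#' Defaults sketch a mid-sized diagnostic capture cohort: 48 samples
#' (half female), 300 targets of 120-400 bp across four autosomes plus
#' chrX/chrY, 250x mean diploid depth with 10% sample-to-sample depth
#' variation and log-normal per-target capture efficiency (sdlog 1.0,
#' i.e. an order-of-magnitude spread across targets, which is what makes
#' raw-count profiles of unrelated capture samples correlate above 0.98),
#' negative-binomial counts (size 200; at 250x this is about twice the
#' Poisson variance), on average 0.5 CNV events per sample with geometric
#' lengths (40% of events span a single target) and 60% deletions, and 4
#' related sample pairs.
#'
#' @param nSamples cohort size.
#' @param sexRatio fraction of female samples.
#' @param nRoisAutosomal,nRoisX,nRoisY target counts per compartment.
#' @param roiLengthRange min/max target length (bp).
#' @param meanDepth expected diploid read count per target.
#' @param depthSampleCV CV of the per-sample depth factor (normal,
#'   truncated at 0.2).
#' @param captureEfficiencySdlog sdlog of the log-normal per-target
#'   efficiency.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson).
#' @param eventsPerSampleRate Poisson mean of CNV events per sample.
#' @param eventLengthGeometricP geometric parameter of event length in ROI
#'   units (length = 1 + Geometric(p)).
#' @param delFraction fraction of events that are deletions.
#' @param nFamilies number of related sample pairs.
#' @param seed integer seed; every draw derives from it.
#' @return a classed list of settings.
#' @export
simConfig <- function(nSamples = 48L, sexRatio = 0.5,
                      nRoisAutosomal = 280L, nRoisX = 15L, nRoisY = 5L,
                      roiLengthRange = c(120L, 400L), meanDepth = 250,
                      depthSampleCV = 0.1, captureEfficiencySdlog = 1.0,
                      dispersion = 200, eventsPerSampleRate = 0.5,
                      eventLengthGeometricP = 0.4, delFraction = 0.6,
                      nFamilies = 4L, seed = 1L) {
  cfg <- list(nSamples = as.integer(nSamples), sexRatio = sexRatio,
              nRoisAutosomal = as.integer(nRoisAutosomal),
              nRoisX = as.integer(nRoisX), nRoisY = as.integer(nRoisY),
              roiLengthRange = roiLengthRange, meanDepth = meanDepth,
              depthSampleCV = depthSampleCV,
              captureEfficiencySdlog = captureEfficiencySdlog,
              dispersion = dispersion,
              eventsPerSampleRate = eventsPerSampleRate,
              eventLengthGeometricP = eventLengthGeometricP,
              delFraction = delFraction, nFamilies = as.integer(nFamilies),
              seed = as.integer(seed))
  stopifnot(cfg$nSamples > 0, cfg$meanDepth > 0, cfg$dispersion > 0,
            cfg$eventsPerSampleRate >= 0,
            cfg$eventLengthGeometricP > 0, cfg$eventLengthGeometricP <= 1,
            cfg$delFraction >= 0, cfg$delFraction <= 1,
            cfg$roiLengthRange[1] > 0,
            cfg$roiLengthRange[2] >= cfg$roiLengthRange[1])
  structure(cfg, class = "SimConfig")
}

#' Surrogate-caller error profile
#'
#' Controls how a surrogate call set degrades the simulated truth:
#' per-event dropout, per-(sample, ROI) false-call insertion and boundary
#' jitter in ROI units. Default rates echo the per-target false-positive
#' frequencies seen on well-behaved diagnostic panels (a few per thousand
#' units) with a 5% event dropout and one target of boundary slack.
#'
#' @param fnRate per-event dropout probability.
#' @param fpRate per-(sample, ROI) false-call probability.
#' @param boundaryJitter maximum boundary shift in ROI units.
#' @param seed integer seed.
#' @return a classed list.
#' @export
callerErrorProfile <- function(fnRate = 0.05, fpRate = 0.005,
                               boundaryJitter = 1L, seed = 1L) {
  stopifnot(fnRate >= 0, fnRate <= 1, fpRate >= 0, fpRate <= 1,
            boundaryJitter >= 0)
  structure(list(fnRate = fnRate, fpRate = fpRate,
                 boundaryJitter = as.integer(boundaryJitter),
                 seed = as.integer(seed)),
            class = "CallerErrorProfile")
}

.simROIs <- function(cfg) {
  autoChroms <- c("chr1", "chr2", "chr7", "chr17")
  nPer <- diff(round(seq(0, cfg$nRoisAutosomal, length.out = 5L)))
  chrom <- c(rep(autoChroms, nPer),
             rep("chrX", cfg$nRoisX), rep("chrY", cfg$nRoisY))
  lens <- sample(cfg$roiLengthRange[1]:cfg$roiLengthRange[2],
                 length(chrom), replace = TRUE)
  starts <- integer(length(chrom))
  pos <- 0L
  for (i in seq_along(chrom)) {
    if (i > 1L && chrom[i] != chrom[i - 1L]) pos <- 0L
    pos <- pos + sample(200:2000, 1L)
    starts[i] <- pos
    pos <- pos + lens[i]
  }
  gr <- GRanges(chrom, IRanges(starts + 1L, starts + lens))
  mcols(gr)$name <- sprintf("ROI%04d", seq_along(gr))
  indexROIs(gr)
}

.simTruthEvents <- function(cfg, rois, samples) {
  chrom <- as.character(seqnames(rois))
  out <- list()
  occupied <- lapply(seq_len(nrow(samples)), function(i) integer())
  for (si in seq_len(nrow(samples))) {
    sex <- samples$sex[si]
    nEv <- stats::rpois(1L, cfg$eventsPerSampleRate)
    allowed <- which(expectedPloidy(chrom, sex) > 0L)
    for (e in seq_len(nEv)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        len <- 1L + stats::rgeom(1L, cfg$eventLengthGeometricP)
        i0 <- sample(allowed, 1L)
        idx <- i0:min(i0 + len - 1L, length(rois))
        idx <- idx[chrom[idx] == chrom[i0]]
        if (any(idx %in% occupied[[si]])) next
        type <- if (stats::runif(1L) < cfg$delFraction) "DEL" else "DUP"
        pl <- expectedPloidy(chrom[i0], sex)
        cn <- if (type == "DEL") {
          if (pl == 1L) 0L
          else if (stats::runif(1L) < 0.1) max(0L, pl - 2L) else pl - 1L
        } else pl + 1L
        occupied[[si]] <- c(occupied[[si]], idx)
        g <- GRanges(chrom[i0],
                     IRanges(start(rois)[idx[1L]],
                             end(rois)[idx[length(idx)]]))
        mcols(g)$type <- type
        mcols(g)$sample <- samples$sample[si]
        mcols(g)$readsRatio <- cn / 2
        mcols(g)$copyNumber <- cn
        mcols(g)$roiIdx <- list(idx)
        out[[length(out) + 1L]] <- g
        placed <- TRUE
        break
      }
      if (!placed)
        warning("could not place a simulated event after 100 retries; skipped")
    }
  }
  if (!length(out)) {
    g <- .emptyCalls(); mcols(g)$roiIdx <- list()
    return(g)
  }
  .bindGRanges(out)
}

#' Simulate a capture cohort with embedded CNVs
#'
#' Lays out non-overlapping targets with random gaps, draws per-sample
#' depth factors and per-target capture efficiencies, embeds DEL/DUP truth
#' events (never overlapping within a sample, respecting each sex's
#' chromosome ploidy) and draws negative-binomial counts with mean
#' \code{meanDepth * depthFactor * efficiency * CN / 2}, i.e. relative to
#' a diploid baseline, so male chrX targets sit near half depth and female
#' chrY targets near zero. Fully reproducible from \code{cfg$seed}.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{rois} (\code{GRanges}), \code{coverage}
#'   (\code{\link{CoverageExperiment}}), \code{truth}
#'   (\code{\link{CNVCallSet}}) and \code{samples} (sample sheet
#'   \code{data.frame}).
#' @export
simulateCohort <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  rois <- .simROIs(cfg)
  nF <- round(cfg$nSamples * cfg$sexRatio)
  samples <- data.frame(
    sample = sprintf("S%03d", seq_len(cfg$nSamples)),
    sex = rep(c("F", "M"), c(nF, cfg$nSamples - nF)),
    family = NA_character_)
  if (cfg$nFamilies > 0L) {
    pairs <- utils::head(seq_len(cfg$nSamples), 2L * cfg$nFamilies)
    samples$family[pairs] <- sprintf("FAM%02d",
                                     rep(seq_len(cfg$nFamilies), each = 2L))
  }
  depthFactor <- pmax(0.2, stats::rnorm(cfg$nSamples, 1, cfg$depthSampleCV))
  efficiency <- stats::rlnorm(length(rois), 0, cfg$captureEfficiencySdlog)
  truth <- .simTruthEvents(cfg, rois, samples)
  chrom <- as.character(seqnames(rois))
  cnMat <- vapply(seq_len(cfg$nSamples),
                  function(si) expectedPloidy(chrom, samples$sex[si]),
                  integer(length(rois)))
  if (length(truth)) {
    tm <- mcols(truth)
    for (i in seq_along(truth)) {
      si <- match(tm$sample[i], samples$sample)
      cnMat[tm$roiIdx[[i]], si] <- tm$copyNumber[i]
    }
  }
  mu <- cfg$meanDepth *
    outer(efficiency, depthFactor) * cnMat / 2
  counts <- matrix(stats::rnbinom(length(mu), size = cfg$dispersion,
                                  mu = mu),
                   nrow = length(rois))
  storage.mode(counts) <- "integer"
  cov <- CoverageExperiment(counts, rois, samples)
  mcols(truth)$roiIdx <- NULL
  list(rois = rois, coverage = cov,
       truth = CNVCallSet("truth", .sortCalls(truth)),
       samples = samples)
}

#' Degrade truth calls into a surrogate caller output
#'
#' Emulates an independent caller's discordance: truth events are dropped
#' with probability \code{fnRate}, surviving events have both boundaries
#' shifted independently by up to \code{boundaryJitter} ROI units (clipped
#' to the chromosome's targets), and false events of 1-2 ROIs with random
#' type are inserted at \code{fpRate} per (sample, ROI) unit on
#' chromosomes where the sample has at least one expected copy.
#' Overlapping same-type calls arising from jitter are merged.
#'
#' @param truth a truth \code{\link{CNVCallSet}} (from
#'   \code{\link{simulateCohort}}).
#' @param profile a \code{\link{callerErrorProfile}}.
#' @param rois targets as \code{GRanges}.
#' @param samples sample sheet \code{data.frame}.
#' @param callerName label for the surrogate call set.
#' @return A \code{\link{CNVCallSet}}.
#' @export
perturbCalls <- function(truth, profile, rois, samples,
                         callerName = "surrogate") {
  stopifnot(inherits(profile, "CallerErrorProfile"))
  set.seed(profile$seed)
  chrom <- as.character(seqnames(rois))
  tg <- cnvCalls(truth)
  out <- list()
  for (i in seq_along(tg)) {
    if (stats::runif(1L) < profile$fnRate) next
    hit <- which(chrom == as.character(seqnames(tg[i])) &
                 start(rois) <= end(tg[i]) & end(rois) >= start(tg[i]))
    lo0 <- min(hit); hi0 <- max(hit)
    lo <- lo0; hi <- hi0
    chromIdx <- which(chrom == chrom[lo])
    j <- profile$boundaryJitter
    if (j > 0L) {
      lo <- lo + sample(seq(-j, j), 1L)
      hi <- hi + sample(seq(-j, j), 1L)
      if (hi < lo) { tmp <- lo; lo <- hi; hi <- tmp }
      ## jitter disagrees about boundaries but never moves a call off its
      ## locus: the perturbed call keeps at least one true target
      lo <- min(lo, hi0); hi <- max(hi, lo0)
      lo <- max(min(chromIdx), lo); hi <- min(max(chromIdx), hi)
    }
    g <- GRanges(chrom[lo], IRanges(start(rois)[lo], end(rois)[hi]))
    mcols(g)$type <- mcols(tg)$type[i]
    mcols(g)$sample <- mcols(tg)$sample[i]
    out[[length(out) + 1L]] <- g
  }
  if (profile$fpRate > 0) {
    for (si in seq_len(nrow(samples))) {
      pl <- expectedPloidy(chrom, samples$sex[si])
      eligible <- which(pl > 0L)
      ins <- eligible[stats::runif(length(eligible)) < profile$fpRate]
      for (i0 in ins) {
        len <- sample(1:2, 1L)
        i1 <- min(i0 + len - 1L, length(rois))
        if (chrom[i1] != chrom[i0]) i1 <- i0
        g <- GRanges(chrom[i0], IRanges(start(rois)[i0], end(rois)[i1]))
        mcols(g)$type <- sample(c("DEL", "DUP"), 1L)
        mcols(g)$sample <- samples$sample[si]
        out[[length(out) + 1L]] <- g
      }
    }
  }
  if (!length(out)) return(CNVCallSet(callerName))
  calls <- .bindGRanges(out)
  ## merge overlaps within sample/type so the call-set invariant holds
  key <- paste(mcols(calls)$sample, mcols(calls)$type, sep = "\r")
  merged <- list()
  for (k in unique(key)) {
    g <- reduce(calls[key == k])
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    mcols(g)$type <- parts[2L]
    mcols(g)$sample <- parts[1L]
    merged[[length(merged) + 1L]] <- g
  }
  CNVCallSet(callerName, .sortCalls(.bindGRanges(merged)))
}
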