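## Coordinate convention: BED input/output is 0-based half-open; in memory
## everything is a GRanges (1-based closed), so widths and overlap lengths
## agree with the BED arithmetic.

#' ROI keys
#'
#' Canonical "chrom:start-end" key of a target region, printed in BED
#' (0-based half-open) coordinates; used to key coverage-matrix rows and
#' no-call units.
#'
#' @param gr a \code{GRanges}.
#' @return character vector of keys.
#' @export
roiKey <- function(gr) {
  sprintf("%s:%d-%d", as.character(seqnames(gr)), start(gr) - 1L, end(gr))
}

#' Pairwise overlap length of genomic intervals
#'
#' Length in bp of the intersection of two intervals; 0 when they do not
#' overlap or lie on different chromosomes. Adjacent intervals (one ending
#' where the other starts, in half-open terms) overlap by 0.
#'
#' @param a,b \code{GRanges} of equal length (or length 1, recycled).
#' @return integer vector of overlap lengths.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 500))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(301, 700))
#' overlapLength(a, b)  # 200
#' @export
overlapLength <- function(a, b) {
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  ol <- pmax(0L, pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L)
  ol[as.character(seqnames(a)) != as.character(seqnames(b))] <- 0L
  ol
}

#' Mean target size
#'
#' Arithmetic mean length (bp) of the capture targets; the consensus
#' module's default minimum size for a validated CNV.
#'
#' @param rois \code{GRanges} of targets.
#' @return a single numeric.
#' @export
meanROISize <- function(rois) {
  if (length(rois) == 0L)
    stop("empty ROI set: the target file is unusable")
  mean(width(rois))
}

.chromClass <- function(chrom) {
  core <- sub("^[Cc]hr", "", chrom)
  ifelse(core == "X", "X", ifelse(core == "Y", "Y", "autosome"))
}

#' Is a chromosome a sex chromosome?
#' @param chrom character vector of chromosome names.
#' @return logical vector.
#' @export
isSexChrom <- function(chrom) .chromClass(chrom) != "autosome"

#' Expected copy number of a chromosome given sample sex
#'
#' Autosomes are diploid; chrX is diploid in females and haploid in males;
#' chrY is absent in females and haploid in males.
#'
#' @param chrom chromosome name(s) ("chrX"/"X" style both recognized).
#' @param sex sex code(s), "F" or "M"; "UNKNOWN" is an error on sex
#'   chromosomes (infer or supply sexes first).
#' @return integer vector of expected copy numbers.
#' @examples
#' expectedPloidy("chr7", "M")  # 2
#' expectedPloidy("chrX", "M")  # 1
#' expectedPloidy("chrY", "F")  # 0
#' @export
expectedPloidy <- function(chrom, sex) {
  n <- max(length(chrom), length(sex))
  chrom <- rep_len(chrom, n)
  sex <- rep_len(sex, n)
  cls <- .chromClass(chrom)
  bad <- cls != "autosome" & !(sex %in% c("F", "M"))
  if (any(bad))
    stop("sex is UNKNOWN for a sex-chromosome query; ",
         "provide sexes or run inferSex() first")
  ifelse(cls == "autosome", 2L,
         ifelse(cls == "X", ifelse(sex == "F", 2L, 1L),
                ifelse(sex == "F", 0L, 1L)))
}

## Deterministic chromosome ordering: numbered autosomes first (numeric
## order), then X, Y, then anything else alphabetically.
orderChroms <- function(chroms) {
  core <- sub("^[Cc]hr", "", chroms)
  num <- suppressWarnings(as.numeric(core))
  cls <- ifelse(!is.na(num), 1L, ifelse(core == "X", 2L,
                ifelse(core == "Y", 3L, 4L)))
  chroms[order(cls, num, core)]
}

## Concatenate GRanges that may carry disjoint seqlevels.
.bindGRanges <- function(grl) suppressWarnings(do.call(c, grl))

## Sort + per-chromosome index; assumes disjoint ROIs.
indexROIs <- function(gr) {
  chrom <- as.character(seqnames(gr))
  lev <- orderChroms(unique(chrom))
  o <- order(match(chrom, lev), start(gr))
  gr <- gr[o]
  chrom <- chrom[o]
  idx <- unlist(lapply(split(seq_along(chrom), factor(chrom, levels = lev)),
                       seq_along), use.names = FALSE)
  mcols(gr)$index <- idx
  gr
}
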