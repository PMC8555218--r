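## On-disk artifacts: BED (3+ column target; 5-column call; 7-column final
## call), TSV coverage matrix and TSV sample sheet. All BED coordinates are
## 0-based half-open and files have no header.

.readTsvLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  strsplit(lines, "\t", fixed = TRUE)
}

#' Read a capture-target BED file
#'
#' Parses a 3+ column BED of capture targets (ROIs), sorts by
#' (chromosome, start), assigns per-chromosome ordinal indices and uses the
#' 4th column as the ROI name when present (else the
#' \code{"chrom:start-end"} key). Overlapping targets are merged with a
#' warning so that downstream per-ROI states are unambiguous.
#'
#' @param path BED file path.
#' @return \code{GRanges} with metadata columns \code{name} and
#'   \code{index}.
#' @export
readTargetBed <- function(path) {
  fields <- .readTsvLines(path)
  if (!length(fields)) stop("empty target BED: ", path)
  n <- length(fields)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
  name <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed target BED line %d: fewer than 3 columns", i))
    st <- suppressWarnings(as.integer(f[2L]))
    en <- suppressWarnings(as.integer(f[3L]))
    if (is.na(st) || is.na(en))
      stop(sprintf("malformed target BED line %d: non-integer coordinates", i))
    if (en <= st)
      stop(sprintf("target BED line %d: end (%d) must exceed start (%d)",
                   i, en, st))
    chrom[i] <- f[1L]; s0[i] <- st; e0[i] <- en
    name[i] <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else
      sprintf("%s:%d-%d", f[1L], st, en)
  }
  if (any(!nzchar(chrom))) stop("empty chromosome name in target BED")
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0))
  mcols(gr)$name <- name
  red <- reduce(gr)
  if (length(red) < length(gr)) {
    warning("overlapping target regions merged (",
            length(gr) - length(red), " fewer ROIs)")
    hits <- findOverlaps(red, gr)
    nm <- vapply(split(mcols(gr)$name[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits)),
                 function(x) paste(unique(x), collapse = "|"), character(1))
    mcols(red)$name <- unname(nm)
    gr <- red
  }
  indexROIs(gr)
}

.parseCallFields <- function(fields, path) {
  n <- length(fields)
  chrom <- character(n); s0 <- integer(n); e0 <- integer(n)
  type <- character(n); sample <- character(n)
  ratio <- rep(NA_real_, n); cn <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 5L)
      stop(sprintf("malformed call BED line %d in %s: need >= 5 columns",
                   i, path))
    if (!f[4L] %in% .CNV_TYPES)
      stop(sprintf("unknown CNV type token '%s' at line %d in %s (expected DEL or DUP)",
                   f[4L], i, path))
    st <- suppressWarnings(as.integer(f[2L]))
    en <- suppressWarnings(as.integer(f[3L]))
    if (is.na(st) || is.na(en) || en <= st)
      stop(sprintf("malformed interval at line %d in %s", i, path))
    chrom[i] <- f[1L]; s0[i] <- st; e0[i] <- en
    type[i] <- f[4L]; sample[i] <- f[5L]
    if (length(f) >= 7L) {
      ratio[i] <- as.numeric(f[6L])
      cn[i] <- as.integer(f[7L])
    }
  }
  gr <- GRanges(chrom, IRanges(s0 + 1L, e0))
  mcols(gr)$type <- type
  mcols(gr)$sample <- sample
  mcols(gr)$readsRatio <- ratio
  mcols(gr)$copyNumber <- cn
  gr
}

#' Read a normalized CNV call BED
#'
#' Reads the common 5-column exchange format (chromosome, start, end,
#' DEL|DUP, sample); files written by \code{\link{writeFinalBed}} (7
#' columns, adding reads ratio and copy number) are also accepted. An empty
#' file yields a \code{CNVCallSet} with zero calls, which downstream
#' triggers the two-caller consensus fallback.
#'
#' @param path BED file path.
#' @param callerName label for the originating caller.
#' @return A \code{\link{CNVCallSet}}.
#' @export
readCallsetBed <- function(path, callerName) {
  fields <- .readTsvLines(path)
  if (!length(fields)) return(CNVCallSet(callerName))
  CNVCallSet(callerName, .parseCallFields(fields, path))
}

#' Write CNV calls to BED
#'
#' \code{writeCallsBed} writes the 5-column exchange format.
#' \code{writeFinalBed} writes the fully annotated 7-column format
#' (chromosome, start, end, DEL|DUP, sample, reads ratio to 3 decimals,
#' integer copy number), sorted by (chromosome, start, sample); every call
#' must carry a reads ratio and copy number.
#'
#' @param callset a \code{\link{CNVCallSet}}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCallsBed <- function(callset, path) {
  gr <- .sortCalls(cnvCalls(callset))
  lines <- if (length(gr)) sprintf("%s\t%d\t%d\t%s\t%s",
    as.character(seqnames(gr)), start(gr) - 1L, end(gr),
    mcols(gr)$type, mcols(gr)$sample) else character()
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeCallsBed
#' @export
writeFinalBed <- function(callset, path) {
  gr <- .sortCalls(cnvCalls(callset))
  m <- mcols(gr)
  if (length(gr) && (any(is.na(m$readsRatio)) || any(is.na(m$copyNumber))))
    stop("final calls must all carry a reads ratio and a copy number")
  lines <- if (length(gr)) sprintf("%s\t%d\t%d\t%s\t%s\t%.3f\t%d",
    as.character(seqnames(gr)), start(gr) - 1L, end(gr),
    m$type, m$sample, m$readsRatio, m$copyNumber) else character()
  writeLines(lines, path)
  invisible(path)
}

.sortCalls <- function(gr) {
  if (!length(gr)) return(gr)
  chrom <- as.character(seqnames(gr))
  lev <- orderChroms(unique(chrom))
  gr[order(match(chrom, lev), start(gr), mcols(gr)$sample)]
}

#' Read a sample sheet
#'
#' TSV with header columns \code{sample}, \code{sex}, \code{family}. Sex
#' tokens are F, M or U/UNKNOWN; an empty family field means unrelated.
#'
#' @param path TSV file path.
#' @return \code{data.frame} with columns sample, sex, family.
#' @export
readSampleSheet <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          na.strings = c("", "NA"))
  need <- c("sample", "sex", "family")
  if (!all(need %in% colnames(df)))
    stop("sample sheet needs header columns: sample, sex, family")
  df <- df[, need]
  df$sex <- toupper(df$sex)
  df$sex[df$sex == "U"] <- "UNKNOWN"
  if (!all(df$sex %in% .SEX_CODES))
    stop("sample sheet sex tokens must be F, M or U")
  if (anyDuplicated(df$sample))
    stop("duplicate sample names in sample sheet")
  df
}

#' Read a per-ROI coverage matrix
#'
#' TSV whose header row names the samples and whose first column keys each
#' target region, primarily as \code{"chrom:start-end"} (0-based half-open)
#' with the ROI name accepted as a fallback. Rows and columns are aligned
#' to the supplied target and sample order; unknown ROIs, missing cells and
#' negative counts are errors.
#'
#' @param path TSV file path.
#' @param rois targets from \code{\link{readTargetBed}}.
#' @param samples sample sheet from \code{\link{readSampleSheet}}.
#' @return A \code{\link{CoverageExperiment}}.
#' @export
readCoverageMatrix <- function(path, rois, samples) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("coverage matrix needs a key column and samples")
  keys <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(mat) <- "numeric")
  if (any(is.na(mat))) stop("missing or non-numeric cells in coverage matrix")
  if (any(mat < 0)) stop("negative counts in coverage matrix")
  rk <- roiKey(rois)
  idx <- match(keys, rk)
  byName <- is.na(idx)
  idx[byName] <- match(keys[byName], mcols(rois)$name)
  if (any(is.na(idx))) {
    missing <- keys[is.na(idx)]
    stripped <- sub("^[Cc]hr", "", missing)
    if (any(stripped %in% sub("^[Cc]hr", "", rk)) &&
        !any(missing %in% rk))
      stop("chromosome naming mismatch between coverage matrix and target ",
           "BED ('chr' prefix differs); harmonize the inputs")
    stop("coverage-matrix ROI(s) absent from target BED: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  if (anyDuplicated(idx)) stop("duplicate ROI rows in coverage matrix")
  if (length(idx) != length(rois))
    stop("coverage matrix is missing ", length(rois) - length(idx),
         " target ROI(s)")
  absent <- setdiff(samples$sample, colnames(mat))
  if (length(absent))
    stop("coverage matrix is missing sample column(s): ",
         paste(absent, collapse = ", "))
  mat <- mat[order(idx), samples$sample, drop = FALSE]
  CoverageExperiment(mat, rois, samples)
}

#' Write the per-(sample, region) validation states
#'
#' @param vs a \code{\link{ValidationSet}}.
#' @param path output TSV path (columns sample, region, state).
#' @return the path, invisibly.
#' @export
writeValidationStates <- function(vs, path) {
  st <- validationStates(vs)
  df <- data.frame(sample = rep(rownames(st), times = ncol(st)),
                   region = rep(colnames(st), each = nrow(st)),
                   state = as.vector(st))
  df <- df[order(df$region, df$sample), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
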