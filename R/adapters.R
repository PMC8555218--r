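#' Thresholds for converting log2 depth ratios to copy numbers
#'
#' Adapter configuration used when normalizing external log2-ratio caller
#' output to integer copy numbers. Deletion bands are deliberately strict:
#' CN0 requires log2 <= -2 and CN1 requires -2 < log2 <= -0.4. The
#' duplication entry point (default +0.32, about the lower bound of CN3 on
#' a diploid background) is configurable.
#'
#' @param delLog2CN0 upper log2 bound for CN0 (default -2).
#' @param delLog2CN1 upper log2 bound for CN1 (default -0.4).
#' @param dupLog2Min lower log2 bound for calling a duplication
#'   (default +0.32).
#' @return a classed list of thresholds.
#' @export
adapterConfig <- function(delLog2CN0 = -2.0, delLog2CN1 = -0.4,
                          dupLog2Min = 0.32) {
  if (!(delLog2CN0 < delLog2CN1 && delLog2CN1 < 0 && dupLog2Min > 0))
    stop("thresholds must satisfy delLog2CN0 < delLog2CN1 < 0 < dupLog2Min")
  structure(list(delLog2CN0 = delLog2CN0, delLog2CN1 = delLog2CN1,
                 dupLog2Min = dupLog2Min), class = "AdapterConfig")
}

#' Classify a copy number as DEL, NORMAL or DUP
#'
#' Compares an integer copy number with the expected ploidy of the
#' chromosome given the sample's sex: below expected is a deletion, above
#' a duplication.
#'
#' @param cn nonnegative integer copy number(s).
#' @param chrom chromosome name(s).
#' @param sex sex code(s), F or M.
#' @return character vector over DEL/NORMAL/DUP.
#' @examples
#' cnToType(1, "chr5", "F")  # DEL
#' cnToType(1, "chrX", "M")  # NORMAL
#' @export
cnToType <- function(cn, chrom, sex) {
  if (any(cn < 0)) stop("copy number must be nonnegative")
  pl <- expectedPloidy(chrom, sex)
  if (any(pl == 0L))
    stop("no expected copies of ", paste(unique(chrom[pl == 0L]),
         collapse = ", "), " for this sex; copy-number state is undefined")
  ifelse(cn < pl, "DEL", ifelse(cn > pl, "DUP", "NORMAL"))
}

#' Convert a log2 depth ratio to an integer copy number
#'
#' Applies the banded thresholds of \code{\link{adapterConfig}} on a
#' diploid background; for haploid regions (ploidy 1) the same bands are
#' applied after shifting the ratio by +1 log2 unit. Above the duplication
#' threshold the copy number is \code{round(2 * 2^log2)}.
#'
#' @param log2ratio finite log2 depth ratio(s).
#' @param cfg an \code{\link{adapterConfig}}.
#' @param ploidy 1 or 2.
#' @return integer copy number(s).
#' @export
log2ToCN <- function(log2ratio, cfg = adapterConfig(), ploidy = 2L) {
  if (any(!is.finite(log2ratio))) stop("non-finite log2 ratio")
  stopifnot(all(ploidy %in% c(1L, 2L)))
  x <- log2ratio + ifelse(ploidy == 1L, 1, 0)
  ifelse(x <= cfg$delLog2CN0, 0L,
  ifelse(x <= cfg$delLog2CN1, 1L,
  ifelse(x < cfg$dupLog2Min, 2L,
         as.integer(floor(2 * 2^x + 0.5)))))
}
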