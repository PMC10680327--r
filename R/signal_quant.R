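#' Per-locus RPKM signal
#'
#' Reads (fragments) per kilobase of locus per million mapped reads:
#' \code{count / (width/1000) / (totalMapped/1e6)}, with the overlap
#' count from [countOverlappingFragments()].
#'
#' @param loci \code{GRanges} with positive widths.
#' @param frags a [FragmentSet-class].
#' @param minOverlap minimum fragment/locus overlap in bases.
#' @return Numeric vector of RPKM values, parallel to \code{loci}.
#' @examples
#' loc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
#' fr <- FragmentSet("s1", "H3K27ac",
#'   GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 700)), 1e7)
#' rpkm(loc, fr)  # 1 fragment / 1 kb / 10 M reads = 0.1
#' @export
rpkm <- function(loci, frags, minOverlap = 1L) {
  stopifnot(methods::is(frags, "FragmentSet"))
  if (any(GenomicRanges::width(loci) < 1L))
    stop("zero-length locus: RPKM is undefined")
  n <- countOverlappingFragments(loci, frags, minOverlap)
  n / (GenomicRanges::width(loci) / 1000) / (totalMapped(frags) / 1e6)
}

#' Build a loci x samples RPKM matrix
#'
#' @param loci \code{GRanges} of quantified loci.
#' @param fragmentSets list of [FragmentSet-class], one per sample, all of
#'   the same mark; column order follows the list order.
#' @param tissues optional character vector parallel to
#'   \code{fragmentSets} (\code{"native"}/\code{"tumor"}), stored in
#'   \code{colData}.
#' @param minOverlap minimum fragment/locus overlap in bases.
#' @return A \code{RangedSummarizedExperiment} with assay \code{"rpkm"},
#'   \code{rowRanges = loci}, and per-sample \code{sample_id},
#'   \code{tissue}, \code{mark}, \code{total_mapped} in \code{colData}.
#' @export
buildSignalMatrix <- function(loci, fragmentSets, tissues = NULL,
                              minOverlap = 1L) {
  stopifnot(length(fragmentSets) > 0L)
  marks <- vapply(fragmentSets, chipMark, character(1))
  if (length(unique(marks)) != 1L)
    stop("all fragment sets must share the same mark")
  ids <- vapply(fragmentSets, sampleId, character(1))
  vals <- vapply(fragmentSets, function(f) rpkm(loci, f, minOverlap),
                 numeric(length(loci)))
  vals <- matrix(vals, nrow = length(loci), ncol = length(fragmentSets),
                 dimnames = list(NULL, ids))
  cd <- S4Vectors::DataFrame(
    sample_id = ids,
    tissue = if (is.null(tissues)) rep(NA_character_, length(ids)) else
      tissues,
    mark = marks,
    total_mapped = vapply(fragmentSets, totalMapped, numeric(1)),
    row.names = ids)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = vals), rowRanges = loci, colData = cd)
}

#' Fold change with a pseudocount
#'
#' \code{(tumor + pseudocount) / (native + pseudocount)}. With
#' \code{pseudocount = 0} a zero denominator yields \code{Inf}, which
#' downstream callers treat as exceeding any threshold.
#'
#' @param tumor,native non-negative signal values (vectorized).
#' @param pseudocount non-negative stabilizer, default 0.5.
#' @return Numeric vector of fold changes.
#' @export
foldChange <- function(tumor, native, pseudocount = 0.5) {
  if (any(tumor < 0, na.rm = TRUE) || any(native < 0, na.rm = TRUE))
    stop("signal values must be non-negative")
  stopifnot(pseudocount >= 0)
  (tumor + pseudocount) / (native + pseudocount)
}

#' Distribution summaries of per-locus signal by locus group
#'
#' For each group of loci, summarizes the per-locus mean RPKM across the
#' samples of one tissue (or all samples).
#'
#' @param se a \code{RangedSummarizedExperiment} from
#'   [buildSignalMatrix()].
#' @param lociGroups named list mapping group name to locus indices
#'   (integers into \code{se}'s rows) or to a \code{GRanges} whose entries
#'   must match \code{rowRanges(se)} exactly.
#' @param tissue optional tissue to restrict the sample mean to.
#' @return \code{data.frame} with columns \code{group}, \code{n},
#'   \code{q25}, \code{median}, \code{q75}.
#' @export
summarizeGroupSignal <- function(se, lociGroups, tissue = NULL) {
  stopifnot(is.list(lociGroups), length(lociGroups) > 0L,
            !is.null(names(lociGroups)))
  mat <- SummarizedExperiment::assay(se, "rpkm")
  if (!is.null(tissue)) {
    keep <- SummarizedExperiment::colData(se)$tissue == tissue
    if (!any(keep)) stop("no samples of tissue '", tissue, "'")
    mat <- mat[, keep, drop = FALSE]
  }
  perLocus <- rowMeans(mat)
  rows <- lapply(names(lociGroups), function(g) {
    idx <- lociGroups[[g]]
    if (methods::is(idx, "GRanges")) {
      m <- GenomicRanges::match(idx, SummarizedExperiment::rowRanges(se))
      if (anyNA(m)) stop("group '", g, "' contains loci absent from the ",
                         "signal matrix")
      idx <- m
    }
    if (!length(idx)) stop("group '", g, "' is empty")
    if (any(idx < 1L | idx > length(perLocus)))
      stop("group '", g, "' contains out-of-range locus indices")
    qs <- stats::quantile(perLocus[idx], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(idx), q25 = qs[1], median = qs[2],
               q75 = qs[3])
  })
  do.call(rbind, rows)
}
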