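## Interval algebra underlying every calling step. Thin, contract-checked
## wrappers over GenomicRanges/IRanges so the conventions (half-open file
## coordinates, >= minOverlap bp overlap, point-to-edge TSS distance) are
## pinned in one place.

#' Pairwise interval overlap with a minimum-overlap requirement
#'
#' Element-wise test: \code{a[i]} and \code{b[i]} overlap iff they share a
#' chromosome and their intersection spans at least \code{minOverlap}
#' bases. Abutting intervals (zero intersection) never overlap at the
#' default \code{minOverlap = 1}.
#'
#' @param a,b \code{GRanges}, recycled to a common length.
#' @param minOverlap minimum shared bases, an integer >= 1.
#' @return Logical vector.
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' intervalOverlaps(a, b)
#' @export
intervalOverlaps <- function(a, b, minOverlap = 1L) {
  stopifnot(minOverlap >= 1L)
  n <- max(length(a), length(b))
  if (length(a) == 1L) a <- rep(a, n)
  if (length(b) == 1L) b <- rep(b, n)
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  ov <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1L
  same & ov >= minOverlap
}

#' Merge intervals within a gap, keeping member provenance
#'
#' Intervals whose separation is at most \code{gap} bases are merged into
#' their union envelope (touching intervals merge at \code{gap = 0}). The
#' output is sorted, pairwise separated by more than \code{gap}, and the
#' operation is idempotent and independent of input order.
#'
#' @param x \code{GRanges}; an optional \code{sample_id} metadata column is
#'   propagated into per-locus member lists.
#' @param gap maximum separation (bases) merged across; integer >= 0.
#' @return \code{GRanges} of merged loci with metadata columns
#'   \code{revmap} (indices of member intervals in the sorted input) and,
#'   when available, \code{memberSamples} (unique contributing sample ids).
#' @export
mergeIntervals <- function(x, gap = 0L) {
  stopifnot(gap >= 0L)
  x <- .sortGR(x)
  merged <- GenomicRanges::reduce(x, min.gapwidth = gap + 1L,
                                  with.revmap = TRUE,
                                  ignore.strand = TRUE)
  sid <- S4Vectors::mcols(x)$sample_id
  if (!is.null(sid)) {
    S4Vectors::mcols(merged)$memberSamples <-
      methods::as(lapply(S4Vectors::mcols(merged)$revmap,
                         function(i) unique(sid[i])), "CharacterList")
  }
  merged
}

#' Minimum distance from intervals to the nearest TSS
#'
#' Distance from an interval to a TSS point is 0 when the TSS lies inside
#' the interval, and the coordinate difference to the nearest interval
#' edge otherwise (a TSS one base outside has distance 1). Intervals on a
#' chromosome with no TSS get \code{Inf} and an \code{NA} gene.
#'
#' @param x \code{GRanges}.
#' @param model a [GeneModel-class].
#' @return \code{data.frame} with columns \code{distance} and
#'   \code{gene_id} (a nearest gene), one row per interval.
#' @export
minDistanceToTSS <- function(x, model) {
  tss <- geneTSS(model)
  if (!length(tss)) stop("gene model has no TSS")
  out <- data.frame(distance = rep(Inf, length(x)),
                    gene_id = rep(NA_character_, length(x)))
  if (!length(x)) return(out)
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(x, tss, ignore.strand = TRUE))
  qh <- S4Vectors::queryHits(hits)
  d <- S4Vectors::mcols(hits)$distance
  inside <- suppressWarnings(
    IRanges::overlapsAny(x, tss, ignore.strand = TRUE))
  ## GRanges distance counts the bases strictly between the ranges; the
  ## coordinate-difference convention used here adds 1 when disjoint
  out$distance[qh] <- ifelse(inside[qh], 0, d + 1)
  out$gene_id[qh] <- names(tss)[S4Vectors::subjectHits(hits)]
  out
}

#' Count fragments overlapping each locus
#'
#' @param loci \code{GRanges}.
#' @param frags a [FragmentSet-class] or \code{GRanges}.
#' @param minOverlap minimum shared bases for a fragment to count.
#' @return Integer vector parallel to \code{loci}.
#' @export
countOverlappingFragments <- function(loci, frags, minOverlap = 1L) {
  stopifnot(minOverlap >= 1L)
  gr <- if (methods::is(frags, "FragmentSet")) fragments(frags) else frags
  GenomicRanges::countOverlaps(loci, gr, minoverlap = minOverlap,
                               ignore.strand = TRUE)
}
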