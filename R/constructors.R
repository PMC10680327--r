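#' Construct a PeakSet
#'
#' @param sampleId sample identifier.
#' @param mark ChIP mark, one of \code{"H3K27ac"}, \code{"H3K4me3"},
#'   \code{"TF"}.
#' @param peaks a \code{GRanges} of peak intervals (1-based, as usual for
#'   \code{GRanges}); sorted on construction.
#' @return A [PeakSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' PeakSet("s1", "H3K27ac", gr)
#' @export
PeakSet <- function(sampleId, mark = c("H3K27ac", "H3K4me3", "TF"), peaks) {
  mark <- match.arg(mark)
  peaks <- .sortGR(peaks)
  methods::new("PeakSet", sampleId = as.character(sampleId), mark = mark,
               peaks = peaks)
}

#' Construct a FragmentSet
#'
#' @inheritParams PeakSet
#' @param fragments a \code{GRanges} of aligned-fragment intervals.
#' @param totalMapped total mapped reads in the library (RPKM denominator);
#'   must be at least \code{length(fragments)}.
#' @return A [FragmentSet-class] object.
#' @export
FragmentSet <- function(sampleId, mark = c("H3K27ac", "H3K4me3", "TF"),
                        fragments, totalMapped) {
  mark <- match.arg(mark)
  methods::new("FragmentSet", sampleId = as.character(sampleId), mark = mark,
               fragments = .sortGR(fragments),
               totalMapped = as.numeric(totalMapped))
}

#' Construct a GeneModel from per-gene spans and exons
#'
#' The TSS is derived from the span and strand: span start on \code{+},
#' span end on \code{-}.
#'
#' @param genes \code{GRanges} of transcript spans with strand, named by
#'   gene id.
#' @param exons \code{GRangesList} parallel to \code{genes} (defaults to
#'   single-exon genes spanning the whole transcript).
#' @return A [GeneModel-class] object.
#' @export
GeneModel <- function(genes, exons = NULL) {
  if (!length(genes))
    return(methods::new("GeneModel", genes = GenomicRanges::GRanges(),
                        tss = GenomicRanges::GRanges(),
                        exons = methods::as(list(), "GRangesList")))
  if (is.null(names(genes)))
    names(genes) <- paste0("gene", seq_along(genes))
  if (is.null(exons))
    exons <- methods::as(GenomicRanges::granges(genes), "GRangesList")
  strand <- as.character(GenomicRanges::strand(genes))
  pos <- ifelse(strand == "+", GenomicRanges::start(genes),
                GenomicRanges::end(genes))
  tss <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(pos, width = 1L),
                                strand = strand)
  names(tss) <- names(genes)
  names(exons) <- names(genes)
  methods::new("GeneModel", genes = genes, tss = tss,
               exons = methods::as(exons, "GRangesList"))
}

#' Construct an EnhancerSet
#'
#' @inheritParams PeakSet
#' @param enhancers \code{GRanges} with a \code{class} metadata column
#'   (\code{"TE"} or \code{"m3E"}); added as all-\code{"TE"} when absent.
#' @param metadata optional list of auxiliary objects.
#' @return An [EnhancerSet-class] object.
#' @export
EnhancerSet <- function(sampleId, enhancers, metadata = list()) {
  if (is.null(S4Vectors::mcols(enhancers)$class))
    S4Vectors::mcols(enhancers)$class <- rep("TE", length(enhancers))
  methods::new("EnhancerSet", sampleId = as.character(sampleId),
               enhancers = enhancers, metadata = metadata)
}

## sort by (chrom, start) with lexicographically ordered seqlevels so the
## result is independent of input order
.sortGR <- function(gr) {
  gr <- GenomeInfoDb::sortSeqlevels(gr)
  sort(gr, ignore.strand = TRUE)
}
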