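## Central S4 containers. All in-memory coordinates are 1-based closed
## (GRanges convention); BED-family files are converted on read/write so
## that user-facing files stay 0-based half-open.

CHIP_MARKS <- c("H3K27ac", "H3K4me3", "TF")
ENHANCER_CLASSES <- c("TE", "m3E")
VARIANT_CLASSES <- c("VEL", "Vm3E", "VSEL")
VARIANT_DIRECTIONS <- c("gain", "lost")
TISSUES <- c("native", "tumor")

#' PeakSet: one sample's peak calls for one histone mark
#'
#' A thin container pairing a sorted \code{GRanges} of peak intervals with
#' the sample identifier and ChIP mark they belong to.
#'
#' @slot sampleId single character, the sample the peaks were called in.
#' @slot mark one of \code{"H3K27ac"}, \code{"H3K4me3"}, \code{"TF"}.
#' @slot peaks sorted \code{GRanges}; optional \code{name}/\code{score}
#'   metadata columns carry through from the source file.
#'
#' @seealso [readPeaks()]
#' @exportClass PeakSet
setClass("PeakSet",
  slots = c(sampleId = "character", mark = "character", peaks = "GRanges"))

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-missing string")
  if (length(object@mark) != 1L || !object@mark %in% CHIP_MARKS)
    msg <- c(msg, sprintf("'mark' must be one of %s",
                          paste(CHIP_MARKS, collapse = ", ")))
  if (length(object@peaks) && is.unsorted(GenomicRanges::order(object@peaks)))
    msg <- c(msg, "'peaks' must be sorted by (chrom, start)")
  if (length(object@peaks) && any(GenomicRanges::start(object@peaks) < 1L))
    msg <- c(msg, "'peaks' must not have negative coordinates")
  if (length(msg)) msg else TRUE
})

#' GeneModel: strand-aware gene annotation with a TSS index
#'
#' Holds one representative transcript per gene (the longest, when several
#' are annotated): its genomic span, strand, transcription start site and
#' exon structure. Used for TSS-distal filtering, genomic-distribution
#' annotation and target-gene assignment.
#'
#' @slot genes \code{GRanges} of transcript spans, one per gene, named by
#'   gene id; strand is \code{+} or \code{-}.
#' @slot tss width-1 \code{GRanges} of transcription start sites, parallel
#'   to \code{genes}: the span start on \code{+}, the span end on \code{-}.
#' @slot exons \code{GRangesList} of exons, parallel to \code{genes}.
#'
#' @seealso [readGeneModel()], [minDistanceToTSS()]
#' @exportClass GeneModel
setClass("GeneModel",
  slots = c(genes = "GRanges", tss = "GRanges", exons = "GRangesList"))

setValidity("GeneModel", function(object) {
  msg <- character()
  n <- length(object@genes)
  if (length(object@tss) != n || length(object@exons) != n)
    msg <- c(msg, "'genes', 'tss' and 'exons' must be parallel")
  if (n) {
    if (is.null(names(object@genes)) || anyDuplicated(names(object@genes)))
      msg <- c(msg, "'genes' must carry unique gene ids as names")
    if (any(GenomicRanges::width(object@tss) != 1L))
      msg <- c(msg, "'tss' entries must have width 1")
    strand <- as.character(GenomicRanges::strand(object@genes))
    if (!all(strand %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    expect <- ifelse(strand == "+",
                     GenomicRanges::start(object@genes),
                     GenomicRanges::end(object@genes))
    if (!all(GenomicRanges::start(object@tss) == expect))
      msg <- c(msg, "TSS must sit at the 5' end of each gene span")
    within <- vapply(seq_len(n), function(i) {
      ex <- object@exons[[i]]
      !length(ex) ||
        (all(GenomicRanges::start(ex) >= GenomicRanges::start(object@genes)[i]) &&
         all(GenomicRanges::end(ex) <= GenomicRanges::end(object@genes)[i]))
    }, logical(1))
    if (!all(within)) msg <- c(msg, "exons must lie within their gene span")
  }
  if (length(msg)) msg else TRUE
})

#' FragmentSet: one sample's aligned fragments for one mark
#'
#' Fragment intervals (sequenced ChIP fragments, as BED-style intervals)
#' plus the library's total mapped read count, the RPKM denominator.
#'
#' @slot sampleId single character.
#' @slot mark one of \code{"H3K27ac"}, \code{"H3K4me3"}, \code{"TF"}.
#' @slot fragments sorted \code{GRanges}.
#' @slot totalMapped single number, total mapped reads in the library;
#'   must be at least the number of fragments held.
#'
#' @seealso [rpkm()], [countOverlappingFragments()]
#' @exportClass FragmentSet
setClass("FragmentSet",
  slots = c(sampleId = "character", mark = "character",
            fragments = "GRanges", totalMapped = "numeric"))

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-missing string")
  if (length(object@mark) != 1L || !object@mark %in% CHIP_MARKS)
    msg <- c(msg, sprintf("'mark' must be one of %s",
                          paste(CHIP_MARKS, collapse = ", ")))
  if (length(object@totalMapped) != 1L || is.na(object@totalMapped) ||
      object@totalMapped <= 0)
    msg <- c(msg, "'totalMapped' must be a single positive number")
  else if (object@totalMapped < length(object@fragments))
    msg <- c(msg, "'totalMapped' must be >= the number of fragments")
  if (length(msg)) msg else TRUE
})

#' EnhancerSet: one sample's called enhancers with class labels
#'
#' Enhancer intervals retained by the TSS-distal filter, labelled
#' \code{"TE"} (typical enhancer) or \code{"m3E"} (H3K4me3-enriched
#' enhancer) in the \code{class} metadata column. Stitched super enhancers
#' are separate merged regions and are returned by
#' [stitchSuperEnhancers()] rather than stored as rows here.
#'
#' @slot sampleId single character.
#' @slot enhancers \code{GRanges} with a \code{class} metadata column.
#' @slot metadata list of auxiliary objects; [callM3Es()] records the
#'   TSS-distal H3K4me3 peaks it used under \code{"h3k4me3Distal"}.
#'
#' @seealso [callActiveEnhancers()], [callM3Es()]
#' @exportClass EnhancerSet
setClass("EnhancerSet",
  slots = c(sampleId = "character", enhancers = "GRanges", metadata = "list"))

setValidity("EnhancerSet", function(object) {
  msg <- character()
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-missing string")
  cls <- S4Vectors::mcols(object@enhancers)$class
  if (length(object@enhancers)) {
    if (is.null(cls))
      msg <- c(msg, "'enhancers' must carry a 'class' metadata column")
    else if (!all(cls %in% ENHANCER_CLASSES))
      msg <- c(msg, sprintf("enhancer class must be one of %s",
                            paste(ENHANCER_CLASSES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' SimConfig: parameters of the synthetic paired-cohort generator
#'
#' Defaults describe the reference simulation: 20 native/tumor pairs,
#' 500 enhancer loci per sample of which 20% are m3Es, 50 planted gain and
#' 20 planted lost variant m3Es at fold change 4 (gain) and 1/4 (lost),
#' each recurring independently in 80% of pairs, negative-binomial fragment
#' counts with dispersion 0.3, and a background per-pair variant rate of
#' 0.02. See the package vignette for the rationale behind each default.
#'
#' @slot seed integer RNG seed; every generator output is a deterministic
#'   function of it.
#' @slot nPairs number of patients (each contributes a native and a tumor
#'   sample).
#' @slot nChroms,chromLengthBp genome shape.
#' @slot nGenes number of genes placed (non-overlapping, with exons).
#' @slot nEnhancersPerSample number of TSS-distal enhancer loci.
#' @slot m3eFraction fraction of enhancer loci that carry an overlapping
#'   TSS-distal H3K4me3 peak.
#' @slot nGainVm3e,nLostVm3e planted variant m3E counts (drawn among m3Es).
#' @slot effectFc true tumor/native fold change of planted gain loci
#'   (lost loci use its reciprocal); 1 yields a null cohort.
#' @slot recurrenceRate per-pair probability that a planted locus carries
#'   its effect in that pair.
#' @slot backgroundVariantRate per-(locus, pair) probability of a sporadic
#'   effect-sized perturbation in a random direction.
#' @slot nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @slot baseRpkmMean expected RPKM of an unperturbed locus.
#' @slot librarySize declared total mapped reads per sample.
#' @slot m3eMe3Ratio H3K4me3 signal of m3E loci relative to TE loci.
#' @slot nSeClusters number of three-enhancer clusters with
#'   \code{seSignalBoost}-fold H3K27ac signal, stitched into super
#'   enhancers downstream.
#' @slot seSignalBoost signal multiplier of super-enhancer constituents.
#' @slot peakJitter per-sample peak-boundary jitter as a fraction of locus
#'   width (models peak-calling variability; 0 disables).
#' @slot fragmentLengthBp length of simulated fragments.
#'
#' @seealso [simConfig()], [generateCohort()]
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(seed = "integer", nPairs = "integer", nChroms = "integer",
            chromLengthBp = "numeric", nGenes = "integer",
            nEnhancersPerSample = "integer", m3eFraction = "numeric",
            nGainVm3e = "integer", nLostVm3e = "integer",
            effectFc = "numeric", recurrenceRate = "numeric",
            backgroundVariantRate = "numeric", nbDispersion = "numeric",
            baseRpkmMean = "numeric", librarySize = "numeric",
            m3eMe3Ratio = "numeric", nSeClusters = "integer",
            seSignalBoost = "numeric", peakJitter = "numeric",
            fragmentLengthBp = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  chk1 <- function(x, nm) if (length(slot(object, x)) != 1L ||
                              is.na(slot(object, x)))
    sprintf("'%s' must be a single non-missing value", nm) else NULL
  for (s in slotNames(object)) msg <- c(msg, chk1(s, s))
  if (length(msg)) return(msg)
  if (object@nPairs < 1L) msg <- c(msg, "'nPairs' must be >= 1")
  counts <- c(nChroms = object@nChroms, nGenes = object@nGenes,
              nEnhancersPerSample = object@nEnhancersPerSample,
              nGainVm3e = object@nGainVm3e, nLostVm3e = object@nLostVm3e,
              nSeClusters = object@nSeClusters)
  if (any(counts < 0L)) msg <- c(msg, "counts must be >= 0")
  if (object@m3eFraction < 0 || object@m3eFraction > 1)
    msg <- c(msg, "'m3eFraction' must lie in [0, 1]")
  if (object@recurrenceRate <= 0 || object@recurrenceRate > 1)
    msg <- c(msg, "'recurrenceRate' must lie in (0, 1]")
  if (object@backgroundVariantRate < 0 || object@backgroundVariantRate >= 1)
    msg <- c(msg, "'backgroundVariantRate' must lie in [0, 1)")
  if (object@effectFc < 1)
    msg <- c(msg, "'effectFc' must be >= 1 (1 = null cohort)")
  if (object@nbDispersion < 0) msg <- c(msg, "'nbDispersion' must be >= 0")
  if (object@baseRpkmMean <= 0) msg <- c(msg, "'baseRpkmMean' must be > 0")
  if (object@librarySize <= 0) msg <- c(msg, "'librarySize' must be > 0")
  if (object@m3eMe3Ratio <= 0) msg <- c(msg, "'m3eMe3Ratio' must be > 0")
  if (object@peakJitter < 0 || object@peakJitter >= 0.5)
    msg <- c(msg, "'peakJitter' must lie in [0, 0.5)")
  if (object@fragmentLengthBp < 1L)
    msg <- c(msg, "'fragmentLengthBp' must be >= 1")
  nM3e <- round(object@m3eFraction * object@nEnhancersPerSample)
  if (object@nGainVm3e + object@nLostVm3e > nM3e)
    msg <- c(msg, sprintf(
      "planted variants (%d) exceed the m3E count implied by m3eFraction (%d)",
      object@nGainVm3e + object@nLostVm3e, nM3e))
  if (length(msg)) msg else TRUE
})
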