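## Generics and accessor methods; slots are never reached into directly
## outside this file.

#' @name accessors
#' @title Accessors for m3Escan containers
#' @description Slot accessors for [PeakSet-class], [FragmentSet-class],
#'   [GeneModel-class] and [EnhancerSet-class] objects.
#' @param x an m3Escan container object.
#' @return The slot content: a character scalar for \code{sampleId} and
#'   \code{chipMark}, a \code{GRanges} for \code{peaks}, \code{fragments},
#'   \code{geneSpans} and \code{geneTSS}, a \code{GRangesList} for
#'   \code{geneExons}, a number for \code{totalMapped}, and the annotated
#'   enhancer \code{GRanges} for \code{enhancers}.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("chipMark", function(x) standardGeneric("chipMark"))
#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))
#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))
#' @rdname accessors
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))
#' @rdname accessors
#' @export
setGeneric("enhancers", function(x) standardGeneric("enhancers"))
#' @rdname accessors
#' @export
setGeneric("geneSpans", function(x) standardGeneric("geneSpans"))
#' @rdname accessors
#' @export
setGeneric("geneTSS", function(x) standardGeneric("geneTSS"))
#' @rdname accessors
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))

#' @rdname accessors
setMethod("sampleId", "PeakSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "FragmentSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "EnhancerSet", function(x) x@sampleId)
#' @rdname accessors
setMethod("chipMark", "PeakSet", function(x) x@mark)
#' @rdname accessors
setMethod("chipMark", "FragmentSet", function(x) x@mark)
#' @rdname accessors
setMethod("peaks", "PeakSet", function(x) x@peaks)
#' @rdname accessors
setMethod("fragments", "FragmentSet", function(x) x@fragments)
#' @rdname accessors
setMethod("totalMapped", "FragmentSet", function(x) x@totalMapped)
#' @rdname accessors
setMethod("enhancers", "EnhancerSet", function(x) x@enhancers)
#' @rdname accessors
setMethod("geneSpans", "GeneModel", function(x) x@genes)
#' @rdname accessors
setMethod("geneTSS", "GeneModel", function(x) x@tss)
#' @rdname accessors
setMethod("geneExons", "GeneModel", function(x) x@exons)

setMethod("length", "PeakSet", function(x) length(x@peaks))
setMethod("length", "FragmentSet", function(x) length(x@fragments))
setMethod("length", "GeneModel", function(x) length(x@genes))
setMethod("length", "EnhancerSet", function(x) length(x@enhancers))

setMethod("show", "PeakSet", function(object) {
  cat(sprintf("PeakSet: %d %s peaks for sample '%s'\n",
              length(object), object@mark, object@sampleId))
})

setMethod("show", "FragmentSet", function(object) {
  cat(sprintf(
    "FragmentSet: %d %s fragments for sample '%s' (%.2fM mapped reads)\n",
    length(object), object@mark, object@sampleId,
    object@totalMapped / 1e6))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel: %d genes on %d sequence(s)\n", length(object),
              length(GenomeInfoDb::seqlevels(object@genes))))
})

setMethod("show", "EnhancerSet", function(object) {
  cls <- S4Vectors::mcols(object@enhancers)$class
  cat(sprintf("EnhancerSet: %d enhancers (%d m3E) for sample '%s'\n",
              length(object), sum(cls == "m3E"), object@sampleId))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d pairs, %d enhancers/sample (m3E fraction %.2f),\n",
    "  %d gain + %d lost planted Vm3Es at FC %.2g, recurrence %.2f,\n",
    "  NB dispersion %.2g, seed %d\n"),
    object@nPairs, object@nEnhancersPerSample, object@m3eFraction,
    object@nGainVm3e, object@nLostVm3e, object@effectFc,
    object@recurrenceRate, object@nbDispersion, object@seed))
})
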