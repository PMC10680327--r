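#' QC-filter cohort samples by peak counts
#'
#' Samples whose peak files hold fewer than the per-mark minimum are
#' excluded, and exclusion removes the whole patient (native/tumor pairing
#' is preserved). Patients present with only one tissue are dropped with
#' a warning.
#'
#' @param manifest a manifest \code{data.frame} from [readManifest()].
#' @param minPeaks minimum peak count; a single number, or a named vector
#'   per mark (e.g. \code{c(H3K27ac = 5000, H3K4me3 = 5000)}).
#' @return A QC report \code{data.frame}: one row per manifest entry with
#'   \code{n_peaks}, \code{included} and \code{reason}.
#' @export
qcFilterSamples <- function(manifest, minPeaks = 5000) {
  counts <- integer(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$peak_path[i]
    if (is.na(p) || !file.exists(p))
      stop("peak file unreadable for patient ", manifest$patient_id[i],
           " (", manifest$tissue[i], ", ", manifest$mark[i], "): ", p)
    counts[i] <- length(readPeaks(p, mark = manifest$mark[i]))
  }
  minFor <- function(mark) {
    if (!is.null(names(minPeaks)) && mark %in% names(minPeaks))
      minPeaks[[mark]] else unname(minPeaks[1])
  }
  low <- counts < vapply(manifest$mark, minFor, numeric(1))

  rep <- data.frame(manifest[, c("patient_id", "tissue", "mark")],
                    n_peaks = counts, included = TRUE,
                    reason = "", stringsAsFactors = FALSE)
  lowPatients <- unique(manifest$patient_id[low])
  unpaired <- unique(manifest$patient_id[
    !vapply(manifest$patient_id, function(p)
      all(TISSUES %in% manifest$tissue[manifest$patient_id == p &
                                         manifest$mark == "H3K27ac"]),
      logical(1))])
  if (length(unpaired))
    warning("dropping patient(s) with a single tissue: ",
            paste(unpaired, collapse = ", "))
  rep$included <- !(rep$patient_id %in% c(lowPatients, unpaired))
  rep$reason[low] <- "low peak count"
  partner <- !low & rep$patient_id %in% lowPatients
  rep$reason[partner] <- "pair partner excluded"
  rep$reason[rep$patient_id %in% unpaired] <- "missing tissue partner"
  rep
}

#' Call TSS-distal active enhancers from H3K27ac peaks
#'
#' Retains the H3K27ac peaks whose minimum distance to any TSS exceeds
#' \code{tssExclusionBp} (whole-peak rule: every base of a retained peak
#' is farther than the exclusion distance from every TSS). Retained peaks
#' become class-\code{"TE"} enhancers with their original coordinates.
#'
#' @param h3k27ac a [PeakSet-class] of H3K27ac peaks.
#' @param model a [GeneModel-class].
#' @param tssExclusionBp promoter-exclusion distance in bp (default 2000).
#' @return An [EnhancerSet-class]; empty peak sets give an empty set.
#' @export
callActiveEnhancers <- function(h3k27ac, model, tssExclusionBp = 2000) {
  stopifnot(methods::is(h3k27ac, "PeakSet"))
  if (chipMark(h3k27ac) != "H3K27ac")
    warning("calling enhancers from mark '", chipMark(h3k27ac), "'")
  pk <- peaks(h3k27ac)
  if (length(pk)) {
    d <- minDistanceToTSS(pk, model)$distance
    pk <- pk[d > tssExclusionBp]
  }
  S4Vectors::mcols(pk)$class <- rep("TE", length(pk))
  EnhancerSet(sampleId(h3k27ac), pk)
}

#' Classify m3Es: enhancers overlapping TSS-distal H3K4me3 peaks
#'
#' H3K4me3 peaks within \code{tssExclusionBp} of a TSS are discarded (so
#' promoter H3K4me3 never promotes an enhancer); enhancers overlapping at
#' least one remaining peak by \code{minOverlap} bases are relabelled
#' class \code{"m3E"}, keeping their own coordinates. The distal H3K4me3
#' peaks used are recorded in the result's metadata under
#' \code{"h3k4me3Distal"} for fraction statistics.
#'
#' @param enhancerSet an [EnhancerSet-class] from [callActiveEnhancers()]
#'   on the same sample.
#' @param h3k4me3 a [PeakSet-class] of H3K4me3 peaks.
#' @param model a [GeneModel-class].
#' @param tssExclusionBp promoter-exclusion distance in bp.
#' @param minOverlap minimum enhancer/peak overlap in bases.
#' @return The updated [EnhancerSet-class].
#' @export
callM3Es <- function(enhancerSet, h3k4me3, model, tssExclusionBp = 2000,
                     minOverlap = 1L) {
  stopifnot(methods::is(enhancerSet, "EnhancerSet"),
            methods::is(h3k4me3, "PeakSet"))
  me3 <- peaks(h3k4me3)
  if (length(me3)) {
    d <- minDistanceToTSS(me3, model)$distance
    me3 <- me3[d > tssExclusionBp]
  }
  enh <- enhancers(enhancerSet)
  if (length(enh)) {
    hit <- IRanges::overlapsAny(enh, me3, minoverlap = minOverlap,
                                ignore.strand = TRUE)
    S4Vectors::mcols(enh)$class <- ifelse(hit, "m3E", "TE")
  }
  EnhancerSet(sampleId(enhancerSet), enh,
              metadata = c(enhancerSet@metadata,
                           list(h3k4me3Distal = me3)))
}

#' Stitch super enhancers and call them by the rank-signal tangent rule
#'
#' ROSE-style: enhancers within \code{stitchBp} of each other are merged
#' into candidates, candidates are ranked by summed signal, both axes of
#' the rank-signal curve are scaled to [0, 1], and candidates above the
#' first point where the curve's slope exceeds 1 are called super
#' enhancers. Ties are broken by coordinate so the call is deterministic;
#' a flat curve (all candidates equal) yields no super enhancers.
#'
#' @param enhancerSet an [EnhancerSet-class].
#' @param signal numeric per-enhancer signal (e.g. [rpkm()] of the
#'   sample's own H3K27ac fragments), parallel to the enhancers.
#' @param stitchBp stitching distance in bp (default 12500).
#' @return \code{GRanges} of super-enhancer regions with metadata columns
#'   \code{totalSignal}, \code{nConstituents} and \code{revmap} (indices
#'   into the enhancer set); empty when fewer than 3 candidates exist
#'   (with a warning) or no candidate rises above the tangent point.
#' @export
stitchSuperEnhancers <- function(enhancerSet, signal, stitchBp = 12500) {
  enh <- enhancers(enhancerSet)
  stopifnot(length(signal) == length(enh))
  empty <- GenomicRanges::GRanges()
  S4Vectors::mcols(empty)$totalSignal <- numeric(0)
  S4Vectors::mcols(empty)$nConstituents <- integer(0)
  if (!length(enh)) return(empty)
  S4Vectors::mcols(enh)$signal <- signal
  cand <- mergeIntervals(enh, gap = stitchBp)
  sig <- S4Vectors::mcols(enh)$signal
  total <- vapply(S4Vectors::mcols(cand)$revmap,
                  function(i) sum(sig[i]), numeric(1))
  if (length(cand) < 3L) {
    warning("fewer than 3 stitched candidates; no super enhancers called")
    return(empty)
  }
  o <- order(total, as.character(GenomicRanges::seqnames(cand)),
             GenomicRanges::start(cand))
  s <- total[o]
  if (max(s) == min(s)) return(empty)
  n <- length(s)
  y <- (s - min(s)) / (max(s) - min(s))
  x <- seq_len(n) / n
  ## tangent rule: the slope-1 line touches the scaled curve where y - x
  ## is minimal; candidates above that point are super enhancers
  cut <- y[which.min(y - x)]
  keep <- which(y > cut)
  if (!length(keep)) return(empty)
  se <- cand[o][keep]
  S4Vectors::mcols(se)$totalSignal <- s[keep]
  S4Vectors::mcols(se)$nConstituents <-
    lengths(S4Vectors::mcols(se)$revmap)
  .sortGR(se)
}

#' Genomic distribution of loci
#'
#' Assigns each locus exactly one category by any-overlap with priority
#' promoter > exon > intron > intergenic, where promoter is the window
#' within \code{tssExclusionBp} of a TSS and intron is the remainder of a
#' gene span. Counts always sum to the number of loci.
#'
#' @param loci \code{GRanges}.
#' @param model a [GeneModel-class].
#' @param tssExclusionBp promoter half-width in bp.
#' @return Named integer vector over
#'   \code{c("promoter", "exon", "intron", "intergenic")}.
#' @export
annotateGenomicDistribution <- function(loci, model, tssExclusionBp = 2000) {
  cats <- c("promoter", "exon", "intron", "intergenic")
  out <- stats::setNames(integer(4), cats)
  if (!length(loci)) return(out)
  tss <- geneTSS(model)
  prom <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tss),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(tss) - tssExclusionBp),
                     GenomicRanges::start(tss) + tssExclusionBp))
  exon <- unlist(geneExons(model))
  span <- geneSpans(model)
  hitAny <- function(subject) suppressWarnings(
    IRanges::overlapsAny(loci, subject, ignore.strand = TRUE))
  assigned <- ifelse(hitAny(prom), "promoter",
    ifelse(hitAny(exon), "exon",
      ifelse(hitAny(span), "intron", "intergenic")))
  tab <- table(factor(assigned, levels = cats))
  out[cats] <- as.integer(tab[cats])
  out
}
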