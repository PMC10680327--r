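## Variant-locus statistics: per-pair fold-change calls, cohort merging,
## recurrence significance (exact binomial tail against a cohort-estimated
## null, BH-corrected per direction), data-driven or fixed recurrence
## thresholds, and the VEL / Vm3E / VSEL callers built from them.

#' Per-pair variant calls by fold-change threshold
#'
#' A locus is called \code{gain} when its tumor/native fold change is at
#' least \code{fcThreshold} and \code{lost} when its native/tumor fold
#' change is; thresholds above 1 make the directions mutually exclusive.
#'
#' @param loci \code{GRanges} the two signal vectors are aligned to.
#' @param tumorRpkm,nativeRpkm per-locus RPKM in the pair's two tissues.
#' @param fcThreshold fold-change threshold, must exceed 1.
#' @param pseudocount passed to [foldChange()].
#' @return The called subset of \code{loci} with metadata columns
#'   \code{direction} and \code{fc} (tumor/native fold change).
#' @export
callPairwiseVariants <- function(loci, tumorRpkm, nativeRpkm,
                                 fcThreshold = 2, pseudocount = 0.5) {
  if (fcThreshold <= 1)
    stop("'fcThreshold' must exceed 1 (directions would overlap)")
  stopifnot(length(tumorRpkm) == length(loci),
            length(nativeRpkm) == length(loci))
  fc <- foldChange(tumorRpkm, nativeRpkm, pseudocount)
  fcRev <- foldChange(nativeRpkm, tumorRpkm, pseudocount)
  gain <- fc >= fcThreshold
  lost <- fcRev >= fcThreshold
  keep <- gain | lost
  out <- loci[keep]
  S4Vectors::mcols(out)$direction <- ifelse(gain[keep], "gain", "lost")
  S4Vectors::mcols(out)$fc <- fc[keep]
  out
}

#' Merge per-pair variant calls cohort-wide, stratified by direction
#'
#' Gain and lost calls are merged separately; the recurrence of a merged
#' locus is the number of distinct patients contributing at least one
#' overlapping same-direction call (patients, not calls).
#'
#' @param callsList named list, patient id to that pair's called
#'   \code{GRanges} (with a \code{direction} metadata column, as returned
#'   by [callPairwiseVariants()]).
#' @param nPairs number of QC-passing pairs in the cohort.
#' @param gap merge gap in bases, see [mergeIntervals()].
#' @return \code{GRanges} of merged loci with metadata columns
#'   \code{direction}, \code{recurrence}, \code{n_pairs},
#'   \code{member_pairs} (CharacterList) and \code{cohort_fc} (mean of the
#'   member calls' tumor/native fold changes, when available).
#' @export
mergeCohortVariants <- function(callsList, nPairs = length(callsList),
                                gap = 0L) {
  stopifnot(length(callsList) >= 1L, !is.null(names(callsList)))
  pieces <- lapply(names(callsList), function(p) {
    gr <- callsList[[p]]
    if (!length(gr)) return(GenomicRanges::GRanges())
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$direction <- S4Vectors::mcols(gr)$direction
    fc <- S4Vectors::mcols(gr)$fc
    S4Vectors::mcols(out)$fc <- if (is.null(fc)) NA_real_ else fc
    S4Vectors::mcols(out)$sample_id <- rep(p, length(gr))
    out
  })
  all <- suppressWarnings(do.call(c, pieces))
  perDir <- lapply(VARIANT_DIRECTIONS, function(d) {
    sub <- all[S4Vectors::mcols(all)$direction == d]
    if (!length(sub)) return(GenomicRanges::GRanges())
    merged <- mergeIntervals(sub, gap = gap)
    mc <- S4Vectors::mcols(merged)
    out <- GenomicRanges::granges(merged)
    S4Vectors::mcols(out)$direction <- rep(d, length(out))
    S4Vectors::mcols(out)$recurrence <- lengths(mc$memberSamples)
    S4Vectors::mcols(out)$n_pairs <- rep(as.integer(nPairs), length(out))
    S4Vectors::mcols(out)$member_pairs <- mc$memberSamples
    sortedFc <- S4Vectors::mcols(.sortGR(sub))$fc
    S4Vectors::mcols(out)$cohort_fc <- vapply(mc$revmap, function(i)
      mean(sortedFc[i]), numeric(1))
    out
  })
  out <- suppressWarnings(do.call(c, perDir))
  if (!length(out)) return(out)
  stopifnot(all(S4Vectors::mcols(out)$recurrence <= nPairs))
  out
}

#' Estimate the per-pair null variant rate
#'
#' \code{p0 = sum(calls) / sum(tested)}, clamped away from 0 and 1 by
#' one event in the total tested count.
#'
#' @param nCalls per-pair numbers of variant calls.
#' @param nTested per-pair numbers of tested loci.
#' @return A list of class \code{"nullModel"} with elements \code{p0},
#'   \code{nCalls}, \code{nTested}.
#' @export
estimateNull <- function(nCalls, nTested) {
  tot <- sum(nTested)
  if (tot <= 0) stop("zero tested loci: the null rate is undefined")
  p0 <- min(max(sum(nCalls) / tot, 1 / tot), 1 - 1 / tot)
  structure(list(p0 = p0, nCalls = sum(nCalls), nTested = tot),
            class = "nullModel")
}

#' Exact binomial recurrence p-value
#'
#' One-sided upper tail \eqn{P(X \ge k)} with
#' \eqn{X \sim Binomial(n, p_0)}: how often at least \code{k} of \code{n}
#' pairs would call the locus variant by chance.
#'
#' @param k observed recurrence(s), integers with \code{1 <= k <= n}.
#' @param n number of pairs.
#' @param null a \code{"nullModel"} from [estimateNull()], or a bare
#'   per-pair probability in (0, 1).
#' @return Numeric vector of p-values in (0, 1].
#' @export
recurrencePvalue <- function(k, n, null) {
  p0 <- if (is.list(null)) null$p0 else null
  if (length(p0) != 1L || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("null rate p0 must lie strictly in (0, 1)")
  if (any(k < 1L) || any(k > n))
    stop("recurrence k must satisfy 1 <= k <= n")
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Permutation null for recurrence (cross-check)
#'
#' Shuffles each pair's calls across loci independently, pools the
#' permuted recurrence counts into an empirical null, and returns
#' add-one-smoothed upper-tail p-values. Provided as an independent
#' alternative to the binomial null of [recurrencePvalue()].
#'
#' @param callMatrix logical matrix, loci x pairs, TRUE where the pair
#'   called the locus variant.
#' @param nPerm number of permutations.
#' @param seed optional RNG seed for reproducibility.
#' @return Numeric vector of p-values, one per locus (row).
#' @export
recurrencePvaluePermutation <- function(callMatrix, nPerm = 1000,
                                        seed = NULL) {
  stopifnot(is.matrix(callMatrix))
  run <- function() {
    nLoci <- nrow(callMatrix)
    obs <- rowSums(callMatrix)
    pooled <- integer(0)
    for (b in seq_len(nPerm)) {
      perm <- apply(callMatrix, 2, sample)
      pooled <- c(pooled, rowSums(perm))
    }
    vapply(obs, function(k)
      (1 + sum(pooled >= k)) / (1 + length(pooled)), numeric(1))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (delegates to
#' \code{stats::p.adjust(method = "BH")}) with the input-domain checks the
#' pipeline relies on; output preserves input order.
#'
#' @param p p-values in (0, 1].
#' @return Adjusted q-values in (0, 1], in the original order.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select the recurrence threshold by the significant-percentage rule
#'
#' The smallest integer r such that, among loci with recurrence at least
#' r (or strictly above r when \code{inclusive = FALSE}), the fraction
#' with q below \code{qCutoff} reaches
#' \code{significantFractionCutoff}.
#'
#' @param recurrence integer recurrence per locus, or a \code{GRanges}
#'   carrying \code{recurrence} and \code{q_value} metadata columns.
#' @param q q-values parallel to \code{recurrence} (ignored when a
#'   \code{GRanges} is given).
#' @param significantFractionCutoff required significant fraction
#'   (default 0.90).
#' @param qCutoff significance level on q (default 0.05).
#' @param inclusive whether loci with recurrence exactly r count as
#'   passing r (default TRUE).
#' @return The selected integer threshold, or \code{NA} with a warning
#'   when no candidate satisfies the rule.
#' @export
selectRecurrenceThreshold <- function(recurrence, q,
                                      significantFractionCutoff = 0.90,
                                      qCutoff = 0.05, inclusive = TRUE) {
  if (methods::is(recurrence, "GRanges")) {
    q <- S4Vectors::mcols(recurrence)$q_value
    recurrence <- S4Vectors::mcols(recurrence)$recurrence
  }
  if (!length(recurrence)) stop("empty recurrence stratum")
  stopifnot(length(q) == length(recurrence))
  for (r in seq(min(recurrence), max(recurrence))) {
    idx <- if (inclusive) recurrence >= r else recurrence > r
    if (!any(idx)) break
    if (mean(q[idx] < qCutoff) >= significantFractionCutoff)
      return(as.integer(r))
  }
  warning("no recurrence threshold reaches the significant-percentage ",
          "cutoff")
  NA_integer_
}

#' Assemble per-pair locus/signal tables for the cohort callers
#'
#' For each patient, merges the pair's two per-sample locus sets into one
#' coordinate set and quantifies RPKM in both tissues over it.
#'
#' @param lociBySample named list, sample id to \code{GRanges} of that
#'   sample's loci (enhancers, m3Es or super enhancers).
#' @param fragmentSets named list, sample id to [FragmentSet-class]
#'   (H3K27ac fragments).
#' @param pairs \code{data.frame} with columns \code{patient_id},
#'   \code{native}, \code{tumor} (the two sample ids).
#' @param gap merge gap in bases for the within-pair union.
#' @return Named list (by patient) of lists with elements \code{loci},
#'   \code{tumor}, \code{native}.
#' @export
buildPairSignals <- function(lociBySample, fragmentSets, pairs, gap = 0L) {
  stopifnot(all(c("patient_id", "native", "tumor") %in% names(pairs)))
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    nid <- pairs$native[i]; tid <- pairs$tumor[i]
    for (id in c(nid, tid)) {
      if (is.null(lociBySample[[id]]))
        stop("no loci for sample '", id, "'")
      if (is.null(fragmentSets[[id]]))
        stop("no fragments for sample '", id, "'")
    }
    loci <- GenomicRanges::granges(mergeIntervals(
      c(GenomicRanges::granges(lociBySample[[nid]]),
        GenomicRanges::granges(lociBySample[[tid]])), gap = gap))
    list(loci = loci,
         tumor = rpkm(loci, fragmentSets[[tid]]),
         native = rpkm(loci, fragmentSets[[nid]]))
  })
  names(out) <- pairs$patient_id
  out
}

## shared engine behind callVELs / callVSELs
.callRecurrentVariants <- function(pairSignals, fcThreshold,
                                   significantFractionCutoff, qCutoff,
                                   pseudocount, gap, inclusive,
                                   fixedRecurrence, class) {
  n <- length(pairSignals)
  if (n < 3L)
    stop("at least 3 pairs are required for recurrence calling")
  calls <- lapply(pairSignals, function(ps)
    callPairwiseVariants(ps$loci, ps$tumor, ps$native, fcThreshold,
                         pseudocount))
  tested <- vapply(pairSignals, function(ps) length(ps$loci), integer(1))
  merged <- mergeCohortVariants(calls, nPairs = n, gap = gap)
  thresholds <- stats::setNames(rep(NA_integer_, 2), VARIANT_DIRECTIONS)
  if (!length(merged)) {
    warning("no per-pair variant calls; returning an empty set")
    S4Vectors::metadata(merged)$thresholds <- thresholds
    return(merged)
  }
  kept <- list()
  for (d in VARIANT_DIRECTIONS) {
    sub <- merged[S4Vectors::mcols(merged)$direction == d]
    if (!length(sub)) next
    nCallsDir <- vapply(calls, function(gr)
      sum(S4Vectors::mcols(gr)$direction == d), integer(1))
    null <- estimateNull(nCallsDir, tested)
    k <- S4Vectors::mcols(sub)$recurrence
    p <- recurrencePvalue(k, n, null)
    q <- bhAdjust(p)
    S4Vectors::mcols(sub)$p_value <- p
    S4Vectors::mcols(sub)$q_value <- q
    r <- if (!is.null(fixedRecurrence)) as.integer(fixedRecurrence) else
      selectRecurrenceThreshold(k, q, significantFractionCutoff, qCutoff,
                                inclusive)
    thresholds[d] <- r
    if (is.na(r)) {
      warning("direction '", d, "': no recurrence threshold selected; ",
              "no loci called")
      next
    }
    keep <- if (inclusive) k >= r else k > r
    kept[[d]] <- sub[keep]
  }
  out <- if (length(kept)) suppressWarnings(do.call(c, unname(kept))) else
    merged[0]
  if (length(out)) {
    S4Vectors::mcols(out)$class <- rep(class, length(out))
    out <- .sortGR(out)
  }
  S4Vectors::metadata(out)$thresholds <- thresholds
  out
}

#' Call recurrent variant enhancer loci (VELs)
#'
#' Full pipeline over per-pair enhancer signal: per-pair fold-change
#' calls, direction-stratified cohort merging, exact binomial recurrence
#' p-values against the cohort-estimated null, BH correction per
#' direction, data-driven recurrence-threshold selection by the
#' significant-percentage rule, and filtering to loci at or above the
#' selected threshold.
#'
#' @param pairSignals per-pair locus/signal tables from
#'   [buildPairSignals()]; at least 3 pairs.
#' @param fcThreshold per-pair fold-change threshold (default 2).
#' @param significantFractionCutoff,qCutoff threshold-selection rule, see
#'   [selectRecurrenceThreshold()].
#' @param pseudocount fold-change pseudocount.
#' @param gap cohort merge gap in bases.
#' @param inclusive recurrence-threshold comparison, see
#'   [selectRecurrenceThreshold()].
#' @return \code{GRanges} of VELs with the variant-locus schema
#'   (\code{direction}, \code{recurrence}, \code{n_pairs}, \code{p_value},
#'   \code{q_value}, \code{cohort_fc}, \code{class}, \code{member_pairs});
#'   the selected per-direction thresholds are in
#'   \code{S4Vectors::metadata(.)$thresholds}.
#' @export
callVELs <- function(pairSignals, fcThreshold = 2,
                     significantFractionCutoff = 0.90, qCutoff = 0.05,
                     pseudocount = 0.5, gap = 0L, inclusive = TRUE) {
  .callRecurrentVariants(pairSignals, fcThreshold,
                         significantFractionCutoff, qCutoff, pseudocount,
                         gap, inclusive, fixedRecurrence = NULL,
                         class = "VEL")
}

#' Call variant super-enhancer loci (VSELs)
#'
#' Same pipeline as [callVELs()] but run on super-enhancer loci with a
#' fixed recurrence threshold instead of data-driven selection.
#'
#' @inheritParams callVELs
#' @param recurrenceThreshold fixed recurrence threshold (default 5).
#' @return \code{GRanges} of VSELs with the variant-locus schema.
#' @export
callVSELs <- function(pairSignals, recurrenceThreshold = 5,
                      fcThreshold = 2, pseudocount = 0.5, gap = 0L,
                      inclusive = TRUE) {
  .callRecurrentVariants(pairSignals, fcThreshold,
                         significantFractionCutoff = NA, qCutoff = NA,
                         pseudocount = pseudocount, gap = gap,
                         inclusive = inclusive,
                         fixedRecurrence = recurrenceThreshold,
                         class = "VSEL")
}

#' Call variant m3Es (Vm3Es)
#'
#' Two-stage composition: stage 1 calls per-pair candidates on each
#' pair's merged m3E loci at fold change \code{pairFc}; stage 2 merges all
#' m3Es cohort-wide, computes the cohort mean tumor and mean native RPKM
#' per merged locus, and calls a locus gain when its mean fold change is
#' at least \code{cohortFc} (lost when at most \code{1/cohortFc}) AND it
#' overlaps at least one stage-1 candidate of that direction. Recurrence
#' (patients with an overlapping same-direction candidate) is recorded,
#' with binomial/BH significance for reporting; an optional recurrence
#' filter is off by default.
#'
#' @param m3eLoci named list, sample id to that sample's m3E \code{GRanges}
#'   (e.g. \code{enhancers(x)[enhancers(x)$class == "m3E"]}).
#' @param fragmentSets named list, sample id to H3K27ac
#'   [FragmentSet-class].
#' @param pairs \code{data.frame} with columns \code{patient_id},
#'   \code{native}, \code{tumor} (sample ids).
#' @param pairFc stage-1 per-pair fold-change threshold (default 2).
#' @param cohortFc stage-2 cohort mean fold-change threshold
#'   (default 1.5).
#' @param pseudocount fold-change pseudocount.
#' @param gap merge gap in bases.
#' @param minOverlap minimum stage-1/stage-2 locus overlap in bases.
#' @param minRecurrence optional minimum recurrence (0 disables; the
#'   default).
#' @return \code{GRanges} of Vm3Es with the variant-locus schema.
#' @export
callVm3Es <- function(m3eLoci, fragmentSets, pairs, pairFc = 2,
                      cohortFc = 1.5, pseudocount = 0.5, gap = 0L,
                      minOverlap = 1L, minRecurrence = 0L) {
  stopifnot(cohortFc > 1, nrow(pairs) >= 1L)
  n <- nrow(pairs)

  ## stage 1: per-pair candidates on the pair's own m3E coordinates
  pairSignals <- buildPairSignals(m3eLoci, fragmentSets, pairs, gap = gap)
  stage1 <- lapply(pairSignals, function(ps)
    callPairwiseVariants(ps$loci, ps$tumor, ps$native, pairFc, pseudocount))
  tested <- vapply(pairSignals, function(ps) length(ps$loci), integer(1))

  ## stage 2: cohort-wide merged m3E coordinates and mean signal
  allM3e <- suppressWarnings(do.call(c, unname(
    lapply(m3eLoci, GenomicRanges::granges))))
  if (!length(allM3e)) {
    warning("no m3E loci in the cohort; returning an empty set")
    return(GenomicRanges::GRanges())
  }
  cohortLoci <- GenomicRanges::granges(mergeIntervals(allM3e, gap = gap))
  sampleIds <- unique(c(pairs$native, pairs$tumor))
  mat <- vapply(sampleIds, function(id)
    rpkm(cohortLoci, fragmentSets[[id]]), numeric(length(cohortLoci)))
  mat <- matrix(mat, nrow = length(cohortLoci),
                dimnames = list(NULL, sampleIds))
  meanT <- rowMeans(mat[, pairs$tumor, drop = FALSE])
  meanN <- rowMeans(mat[, pairs$native, drop = FALSE])
  fc <- foldChange(meanT, meanN, pseudocount)

  out <- list()
  for (d in VARIANT_DIRECTIONS) {
    cands <- lapply(stage1, function(gr)
      gr[S4Vectors::mcols(gr)$direction == d])
    allCand <- suppressWarnings(do.call(c, unname(cands)))
    patientOf <- rep(pairs$patient_id, vapply(cands, length, integer(1)))
    hits <- GenomicRanges::findOverlaps(cohortLoci, allCand,
                                        minoverlap = minOverlap,
                                        ignore.strand = TRUE)
    supPat <- split(patientOf[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits),
                           levels = seq_along(cohortLoci)))
    recurrence <- vapply(supPat, function(p) length(unique(p)), integer(1))
    passFc <- if (d == "gain") fc >= cohortFc else fc <= 1 / cohortFc
    supported <- recurrence >= 1L

    ## significance for reporting, over the supported stratum
    pv <- qv <- rep(NA_real_, length(cohortLoci))
    if (any(supported)) {
      null <- estimateNull(vapply(cands, length, integer(1)), tested)
      pv[supported] <- recurrencePvalue(recurrence[supported], n, null)
      qv[supported] <- bhAdjust(pv[supported])
    }
    keep <- passFc & supported & recurrence >= minRecurrence
    if (!any(keep)) next
    gr <- cohortLoci[keep]
    S4Vectors::mcols(gr)$direction <- rep(d, length(gr))
    S4Vectors::mcols(gr)$recurrence <- recurrence[keep]
    S4Vectors::mcols(gr)$n_pairs <- rep(as.integer(n), length(gr))
    S4Vectors::mcols(gr)$p_value <- pv[keep]
    S4Vectors::mcols(gr)$q_value <- qv[keep]
    S4Vectors::mcols(gr)$cohort_fc <- fc[keep]
    S4Vectors::mcols(gr)$class <- rep("Vm3E", length(gr))
    S4Vectors::mcols(gr)$member_pairs <- methods::as(
      lapply(supPat[keep], unique), "CharacterList")
    out[[d]] <- gr
  }
  if (!length(out)) return(cohortLoci[0])
  .sortGR(suppressWarnings(do.call(c, unname(out))))
}
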