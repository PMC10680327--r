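#' Per-sample enhancer-class fractions
#'
#' Two fractions per sample: the share of called enhancers that are m3Es,
#' and the share of all H3K4me3 peaks that lie on an m3E.
#'
#' @param enhancerSets named list of [EnhancerSet-class] (after
#'   [callM3Es()]), by sample id.
#' @param h3k4me3Peaks named list of [PeakSet-class] holding each sample's
#'   complete H3K4me3 peak set, by the same sample ids.
#' @param minOverlap minimum peak/m3E overlap in bases.
#' @return \code{data.frame} with columns \code{sample_id},
#'   \code{n_enhancers}, \code{n_m3e}, \code{m3e_fraction},
#'   \code{n_h3k4me3_peaks}, \code{h3k4me3_fraction_on_m3e},
#'   \code{flagged} (TRUE when a denominator was zero and the fraction is
#'   \code{NA}).
#' @export
fractionReport <- function(enhancerSets, h3k4me3Peaks, minOverlap = 1L) {
  stopifnot(!is.null(names(enhancerSets)))
  rows <- lapply(names(enhancerSets), function(id) {
    enh <- enhancers(enhancerSets[[id]])
    cls <- S4Vectors::mcols(enh)$class
    nE <- length(enh); nM <- sum(cls == "m3E")
    m3e <- enh[cls == "m3E"]
    pk <- h3k4me3Peaks[[id]]
    nPk <- if (is.null(pk)) 0L else length(pk)
    onM3e <- if (nPk)
      sum(IRanges::overlapsAny(peaks(pk), m3e, minoverlap = minOverlap,
                               ignore.strand = TRUE)) else 0L
    data.frame(sample_id = id, n_enhancers = nE, n_m3e = nM,
               m3e_fraction = if (nE) nM / nE else NA_real_,
               n_h3k4me3_peaks = nPk,
               h3k4me3_fraction_on_m3e = if (nPk) onM3e / nPk else NA_real_,
               flagged = nE == 0L || nPk == 0L)
  })
  do.call(rbind, rows)
}

#' Assign proximal target genes to loci
#'
#' The k nearest TSS within \code{maxDistanceBp} of each locus, distance
#' measured as in [minDistanceToTSS()] (0 when the TSS is inside the
#' locus); ties are broken by (distance, gene id lexicographic). Loci with
#' no TSS in range get an empty assignment.
#'
#' @param loci \code{GRanges}.
#' @param model a [GeneModel-class].
#' @param maxDistanceBp search radius in bp (default 500000).
#' @param kNearest number of genes to assign per locus (default 1).
#' @return A \code{CharacterList} parallel to \code{loci}.
#' @export
assignTargetGenes <- function(loci, model, maxDistanceBp = 5e5,
                              kNearest = 1L) {
  tss <- geneTSS(model)
  if (!length(tss)) stop("gene model is empty")
  hits <- GenomicRanges::findOverlaps(loci, tss,
                                      maxgap = as.integer(maxDistanceBp),
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  pos <- GenomicRanges::start(tss)[sh]
  s <- GenomicRanges::start(loci)[qh]; e <- GenomicRanges::end(loci)[qh]
  d <- ifelse(pos >= s & pos <= e, 0,
              ifelse(pos < s, s - pos, pos - e))
  keep <- d <= maxDistanceBp
  qh <- qh[keep]; sh <- sh[keep]; d <- d[keep]
  gene <- names(tss)[sh]
  res <- rep(list(character(0)), length(loci))
  if (length(qh)) {
    o <- order(qh, d, gene)
    byLocus <- split(seq_along(qh)[o], qh[o])
    for (nm in names(byLocus)) {
      i <- byLocus[[nm]]
      res[[as.integer(nm)]] <- gene[utils::head(i, kNearest)]
    }
  }
  methods::as(res, "CharacterList")
}

#' Compare target-gene expression across enhancer classes
#'
#' Summarizes expression per gene group and tests each pair of groups
#' with a two-sided Mann-Whitney rank-sum test (exact for small groups,
#' normal approximation otherwise).
#'
#' @param groups named list mapping group name (e.g. TE/SE/m3E) to gene
#'   ids.
#' @param expr expression table: a named numeric vector of per-gene
#'   values, or a gene x sample matrix (row means are used).
#' @param exactMax use the exact rank-sum distribution when both group
#'   sizes are at most this (default 8).
#' @return List with \code{summaries} (group, n, n_dropped, q25, median,
#'   q75) and \code{tests} (group1, group2, p) data frames.
#' @export
compareTargetExpression <- function(groups, expr, exactMax = 8L) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  if (is.matrix(expr) || is.data.frame(expr))
    expr <- rowMeans(as.matrix(expr))
  stopifnot(!is.null(names(expr)))
  vals <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (!length(ids)) stop("group '", g, "' is empty")
    expr[ids[ids %in% names(expr)]]
  })
  names(vals) <- names(groups)
  summaries <- do.call(rbind, lapply(names(vals), function(g) {
    v <- vals[[g]]
    qs <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(v),
               n_dropped = length(groups[[g]]) - length(v),
               q25 = qs[1], median = qs[2], q75 = qs[3])
  }))
  cmb <- utils::combn(names(vals), 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(cmb, function(pr) {
    a <- vals[[pr[1]]]; b <- vals[[pr[2]]]
    exact <- length(a) <= exactMax && length(b) <= exactMax
    p <- suppressWarnings(stats::wilcox.test(
      a, b, alternative = "two.sided", exact = exact, correct = TRUE))
    data.frame(group1 = pr[1], group2 = pr[2], p = p$p.value)
  }))
  list(summaries = summaries, tests = tests)
}

#' PCA sample classification over variant-locus signal
#'
#' Samples are projected onto the top principal components of the
#' per-locus-centered \code{log2(RPKM + 1)} matrix (no unit-variance
#' scaling). Component signs are fixed so the largest-magnitude loading
#' of each component is positive, making the coordinates deterministic.
#'
#' @param se a \code{RangedSummarizedExperiment} from
#'   [buildSignalMatrix()] (typically over Vm3E loci).
#' @param nComponents number of components to return.
#' @param logTransform apply \code{log2(x + 1)} first (default TRUE).
#' @param center remove the per-locus mean (default TRUE).
#' @return \code{data.frame} with \code{sample_id}, \code{tissue}, one
#'   column per component (\code{PC1}, ...), and the proportion of
#'   variance per component as the \code{"varExplained"} attribute.
#' @export
pcaClassification <- function(se, nComponents = 2L, logTransform = TRUE,
                              center = TRUE) {
  mat <- SummarizedExperiment::assay(se, "rpkm")
  if (ncol(mat) < 2L || nrow(mat) < 2L)
    stop("PCA needs at least 2 samples and 2 loci")
  if (logTransform) mat <- log2(mat + 1)
  m <- t(mat)                               # samples x loci
  if (center) m <- sweep(m, 2, colMeans(m))
  k <- min(nComponents, dim(m) - c(1L, 0L))[1]
  sv <- svd(m, nu = k, nv = k)
  if (max(sv$d) < 1e-12) {
    warning("constant signal matrix; all PCA coordinates are zero")
    coords <- matrix(0, nrow(m), k)
  } else {
    flip <- vapply(seq_len(k), function(j) {
      v <- sv$v[, j]
      sign(v[which.max(abs(v))])
    }, numeric(1))
    coords <- sv$u[, seq_len(k), drop = FALSE] %*%
      diag(sv$d[seq_len(k)], k) %*% diag(flip, k)
  }
  cd <- SummarizedExperiment::colData(se)
  out <- data.frame(sample_id = cd$sample_id, tissue = cd$tissue)
  for (j in seq_len(k)) out[[paste0("PC", j)]] <- coords[, j]
  attr(out, "varExplained") <- (sv$d^2 / sum(sv$d^2))[seq_len(k)]
  out
}

#' Transcription-factor overlap trend across timepoints
#'
#' For each condition/timepoint, the fraction of m3Es overlapped by at
#' least one TF peak, with a parallel column for all enhancers.
#'
#' @param m3eSets named list (by timepoint) of m3E \code{GRanges}.
#' @param enhancerSets named list (same timepoints) of enhancer
#'   \code{GRanges}.
#' @param tfPeaks a [PeakSet-class] or \code{GRanges} of TF binding sites.
#' @param minOverlap minimum overlap in bases.
#' @return \code{data.frame} with \code{timepoint},
#'   \code{m3e_tf_fraction}, \code{enhancer_tf_fraction} (\code{NA} and
#'   flagged when a timepoint has zero loci).
#' @export
tfOverlapTrend <- function(m3eSets, enhancerSets, tfPeaks,
                           minOverlap = 1L) {
  stopifnot(!is.null(names(m3eSets)),
            identical(names(m3eSets), names(enhancerSets)))
  tf <- if (methods::is(tfPeaks, "PeakSet")) peaks(tfPeaks) else tfPeaks
  frac <- function(gr) {
    if (!length(gr)) return(NA_real_)
    mean(IRanges::overlapsAny(gr, tf, minoverlap = minOverlap,
                              ignore.strand = TRUE))
  }
  data.frame(
    timepoint = names(m3eSets),
    m3e_tf_fraction = vapply(m3eSets, frac, numeric(1)),
    enhancer_tf_fraction = vapply(enhancerSets, frac, numeric(1)),
    flagged = vapply(m3eSets, length, integer(1)) == 0L,
    row.names = NULL)
}
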