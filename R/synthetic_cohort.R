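## Synthetic paired-cohort generator. Plants TSS-distal enhancer loci
## (with m3E and super-enhancer structure), gain/lost variant m3Es of
## configurable effect size and recurrence, and negative-binomial
## fragment-count noise, so that every pipeline stage can be scored
## against known truth at desk scale.

#' Build a SimConfig
#'
#' See [SimConfig-class] for the meaning and defaults of every parameter.
#'
#' @param seed integer RNG seed.
#' @param nPairs,nChroms,chromLengthBp,nGenes,nEnhancersPerSample cohort
#'   and genome shape.
#' @param m3eFraction,nGainVm3e,nLostVm3e,effectFc,recurrenceRate planted
#'   structure.
#' @param backgroundVariantRate,nbDispersion,baseRpkmMean,librarySize
#'   noise model.
#' @param m3eMe3Ratio,nSeClusters,seSignalBoost,peakJitter,fragmentLengthBp
#'   signal structure details.
#' @return A validated [SimConfig-class] object.
#' @examples
#' simConfig(seed = 1, nPairs = 4, nEnhancersPerSample = 50,
#'           nGainVm3e = 5, nLostVm3e = 2, nGenes = 20, nSeClusters = 1)
#' @export
simConfig <- function(seed = 1L, nPairs = 20L, nChroms = 4L,
                      chromLengthBp = 1e7, nGenes = 200L,
                      nEnhancersPerSample = 500L, m3eFraction = 0.2,
                      nGainVm3e = 50L, nLostVm3e = 20L, effectFc = 4,
                      recurrenceRate = 0.8, backgroundVariantRate = 0.02,
                      nbDispersion = 0.3, baseRpkmMean = 30,
                      librarySize = 1e6, m3eMe3Ratio = 2,
                      nSeClusters = 5L, seSignalBoost = 8,
                      peakJitter = 0.1, fragmentLengthBp = 200L) {
  methods::new("SimConfig", seed = as.integer(seed),
               nPairs = as.integer(nPairs), nChroms = as.integer(nChroms),
               chromLengthBp = as.numeric(chromLengthBp),
               nGenes = as.integer(nGenes),
               nEnhancersPerSample = as.integer(nEnhancersPerSample),
               m3eFraction = m3eFraction,
               nGainVm3e = as.integer(nGainVm3e),
               nLostVm3e = as.integer(nLostVm3e), effectFc = effectFc,
               recurrenceRate = recurrenceRate,
               backgroundVariantRate = backgroundVariantRate,
               nbDispersion = nbDispersion, baseRpkmMean = baseRpkmMean,
               librarySize = librarySize, m3eMe3Ratio = m3eMe3Ratio,
               nSeClusters = as.integer(nSeClusters),
               seSignalBoost = seSignalBoost, peakJitter = peakJitter,
               fragmentLengthBp = as.integer(fragmentLengthBp))
}

#' Generate a synthetic genome annotation
#'
#' Places non-overlapping genes (uniformly within per-chromosome slots,
#' random strand, 2-4 exons each) on \code{nChroms} chromosomes.
#' Deterministic given \code{config@seed}.
#'
#' @param config a [SimConfig-class].
#' @return A [GeneModel-class]; write it with [writeGtf()].
#' @export
generateGenome <- function(config) {
  stopifnot(methods::is(config, "SimConfig"))
  withr::with_seed(config@seed, .generateGenomeInner(config))
}

.generateGenomeInner <- function(config) {
  n <- config@nGenes
  chroms <- paste0("chr", seq_len(config@nChroms))
  if (n == 0L)
    return(GeneModel(GenomicRanges::GRanges()))
  perChrom <- diff(floor(seq(0, n, length.out = config@nChroms + 1L)))
  spans <- list(); exons <- list()
  maxGeneLen <- 8000L
  for (ci in seq_along(chroms)) {
    g <- perChrom[ci]
    if (!g) next
    slot <- floor(config@chromLengthBp / g)
    if (slot < maxGeneLen + 2000L)
      stop("infeasible packing: too many genes for the genome length")
    for (i in seq_len(g)) {
      len <- sample(3000:maxGeneLen, 1L)
      lo <- (i - 1L) * slot + 1L
      start <- lo + sample.int(slot - len - 1000L, 1L)
      end <- start + len - 1L
      strand <- sample(c("+", "-"), 1L)
      nEx <- sample(2:4, 1L)
      p <- sort(sample((start + 50L):(end - 50L), 2L * nEx - 2L))
      bounds <- c(start, p, end)
      exStart <- bounds[seq(1L, by = 2L, length.out = nEx)]
      exEnd <- bounds[seq(2L, by = 2L, length.out = nEx)]
      cf <- factor(chroms[ci], levels = chroms)
      spans[[length(spans) + 1L]] <- GenomicRanges::GRanges(
        cf, IRanges::IRanges(start, end), strand = strand)
      exons[[length(exons) + 1L]] <- GenomicRanges::GRanges(
        cf, IRanges::IRanges(exStart, exEnd), strand = strand)
    }
  }
  genes <- unlist(methods::as(spans, "GRangesList"))
  names(genes) <- sprintf("g%04d", seq_along(genes))
  exl <- methods::as(exons, "GRangesList")
  names(exl) <- names(genes)
  GeneModel(genes, exl)
}

## sample starts of TSS-distal blocks of the given width; plain
## data.frame (chrom index, start) to keep the rejection loop cheap
.sampleDistalStarts <- function(nWanted, width, tss, chromLens, marginBp,
                                maxIter = 60L) {
  tssBy <- split(GenomicRanges::start(tss),
                 as.character(GenomicRanges::seqnames(tss)))
  got <- data.frame(chrom = integer(0), start = numeric(0))
  for (it in seq_len(maxIter)) {
    if (nrow(got) >= nWanted) break
    nDraw <- max(200L, 4L * (nWanted - nrow(got)))
    ci <- sample(seq_along(chromLens), nDraw, replace = TRUE,
                 prob = chromLens)
    st <- 1 + floor(stats::runif(nDraw) * (chromLens[ci] - width - 1))
    ## distal iff no TSS within marginBp of any base of the block
    ok <- vapply(seq_len(nDraw), function(i) {
      tp <- tssBy[[names(chromLens)[ci[i]]]]
      is.null(tp) || !any(tp >= st[i] - marginBp &
                            tp <= st[i] + width - 1 + marginBp)
    }, logical(1))
    got <- rbind(got, data.frame(chrom = ci[ok], start = st[ok]))
  }
  got[order(got$chrom, got$start), , drop = FALSE]
}

## greedy left-to-right selection with a minimum inter-block spacing
.greedySpace <- function(cand, widths, minGap, nWanted,
                         avoid = NULL, avoidGap = 0) {
  keep <- integer(0)
  lastEnd <- -Inf; lastChrom <- -1L
  for (i in seq_len(nrow(cand))) {
    if (length(keep) >= nWanted) break
    w <- widths[length(keep) + 1L]
    s <- cand$start[i]; ch <- cand$chrom[i]
    if (ch != lastChrom) lastEnd <- -Inf
    if (s <= lastEnd + minGap) next
    if (!is.null(avoid)) {
      av <- avoid[avoid$chrom == ch, , drop = FALSE]
      if (nrow(av) && any(s + w - 1 >= av$start - avoidGap &
                            s <= av$end + avoidGap)) next
    }
    keep <- c(keep, i)
    lastEnd <- s + w - 1; lastChrom <- ch
  }
  keep
}

.placeEnhancerLoci <- function(config, model) {
  tss <- geneTSS(model)
  chroms <- paste0("chr", seq_len(config@nChroms))
  chromLens <- stats::setNames(rep(config@chromLengthBp, config@nChroms),
                               chroms)
  marginBp <- 2000 + 300           # distal even after +/-10% peak jitter
  nSe <- config@nSeClusters
  nSingle <- config@nEnhancersPerSample - 3L * nSe
  if (nSingle < 0L) stop("nSeClusters too large for nEnhancersPerSample")

  clusterExtent <- 8000L + 800L
  anchors <- data.frame(chrom = integer(0), start = numeric(0))
  if (nSe > 0L) {
    cand <- .sampleDistalStarts(8L * nSe, clusterExtent, tss, chromLens,
                                marginBp)
    keep <- .greedySpace(cand, rep(clusterExtent, nSe), 40000, nSe)
    if (length(keep) < nSe)
      stop("infeasible packing: could not place super-enhancer clusters")
    anchors <- cand[keep, , drop = FALSE]
    anchors$end <- anchors$start + clusterExtent - 1
  }

  widths <- sample(600:1500, max(nSingle, 1L), replace = TRUE)
  cand <- .sampleDistalStarts(6L * nSingle, 1500L, tss, chromLens,
                              marginBp)
  ## singleton loci sit farther apart than the 12.5 kb stitch distance so
  ## super-enhancer structure exists only where clusters are planted
  keep <- .greedySpace(cand, widths, 15000, nSingle,
                       avoid = anchors, avoidGap = 15000)
  if (length(keep) < nSingle)
    stop("infeasible packing: could not place ", nSingle,
         " enhancer loci; enlarge the genome")

  mChrom <- rep(anchors$chrom, each = 3L)
  mStart <- rep(anchors$start, each = 3L) + c(0, 4000, 8000)
  sChrom <- cand$chrom[keep]; sStart <- cand$start[keep]
  sWidth <- widths[seq_along(keep)]
  loci <- GenomicRanges::GRanges(
    factor(chroms[c(mChrom, sChrom)], levels = chroms),
    IRanges::IRanges(c(mStart, sStart),
                     width = c(rep(800L, length(mChrom)), sWidth)))
  S4Vectors::mcols(loci)$isSe <- rep(c(TRUE, FALSE),
                                     c(length(mChrom), length(sChrom)))
  loci <- .sortGR(loci)
  S4Vectors::mcols(loci)$locus_id <- sprintf("L%04d", seq_along(loci))
  loci
}

.jitterLoci <- function(gr, frac) {
  if (frac == 0 || !length(gr)) return(gr)
  w <- GenomicRanges::width(gr)
  ds <- round(stats::runif(length(gr), -frac, frac) * w)
  de <- round(stats::runif(length(gr), -frac, frac) * w)
  ns <- pmax(1, GenomicRanges::start(gr) + ds)
  ne <- pmax(ns + 49, GenomicRanges::end(gr) + de)
  GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                         IRanges::IRanges(ns, ne))
}

.nbDraw <- function(n, mu, dispersion) {
  if (dispersion <= 1e-12) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

.fragmentsFromCounts <- function(loci, counts, fragLen) {
  tot <- sum(counts)
  if (!tot) return(GenomicRanges::GRanges())
  idx <- rep(seq_along(loci), counts)
  lo <- GenomicRanges::start(loci)
  hi <- pmax(lo, GenomicRanges::end(loci) - fragLen + 1L)
  s <- lo[idx] + floor(stats::runif(tot) * (hi - lo + 1L)[idx])
  GenomicRanges::GRanges(GenomicRanges::seqnames(loci)[idx],
                         IRanges::IRanges(s, width = fragLen))
}

#' Generate a synthetic paired native/tumor cohort with planted truth
#'
#' Emulates the data structure of a paired tumor/normal histone ChIP-seq
#' cohort: per-sample H3K27ac and H3K4me3 peak sets over shared
#' TSS-distal enhancer loci (boundaries jittered per sample), fragment
#' sets with negative-binomial counts whose means encode the planted
#' m3E / super-enhancer / variant structure, a sample manifest, and a
#' truth table for recovery scoring. Deterministic given
#' \code{config@seed}.
#'
#' @param config a [SimConfig-class].
#' @param dir optional directory; when given, the complete input bundle
#'   (GTF, per-sample peak and fragment BED files, manifest TSV, truth
#'   TSV) is written there and the manifest carries the file paths.
#' @return A list with elements \code{config}, \code{geneModel},
#'   \code{masterLoci}, \code{truth} (a \code{GRanges} with
#'   \code{locus_id}, \code{class}, \code{direction}, \code{true_fc},
#'   \code{recurring_pairs}), \code{peakSets} and \code{fragmentSets}
#'   (nested lists by sample id then mark), \code{pairs} (patient to
#'   sample-id map) and \code{manifest}.
#' @export
generateCohort <- function(config, dir = NULL) {
  stopifnot(methods::is(config, "SimConfig"))
  withr::with_seed(config@seed, .generateCohortInner(config, dir))
}

.generateCohortInner <- function(config, dir) {
  model <- .generateGenomeInner(config)
  loci <- .placeEnhancerLoci(config, model)
  nLoci <- length(loci)
  nPairs <- config@nPairs
  isSe <- S4Vectors::mcols(loci)$isSe

  ## planted classes and directions
  m3eCount <- round(config@m3eFraction * config@nEnhancersPerSample)
  isM3e <- rep(FALSE, nLoci)
  isM3e[sample(which(!isSe), min(m3eCount, sum(!isSe)))] <- TRUE
  direction <- rep("none", nLoci)
  planted <- sample(which(isM3e), config@nGainVm3e + config@nLostVm3e)
  gainIdx <- planted[seq_len(config@nGainVm3e)]
  lostIdx <- setdiff(planted, gainIdx)
  direction[gainIdx] <- "gain"; direction[lostIdx] <- "lost"
  patients <- sprintf("P%02d", seq_len(nPairs))
  recurring <- matrix(FALSE, nLoci, nPairs)
  recurring[planted, ] <- stats::runif(length(planted) * nPairs) <
    config@recurrenceRate

  truth <- GenomicRanges::granges(loci)
  S4Vectors::mcols(truth)$locus_id <- S4Vectors::mcols(loci)$locus_id
  S4Vectors::mcols(truth)$class <- ifelse(isSe, "SE",
                                          ifelse(isM3e, "m3E", "TE"))
  S4Vectors::mcols(truth)$direction <- direction
  S4Vectors::mcols(truth)$true_fc <- ifelse(direction == "gain",
    config@effectFc, ifelse(direction == "lost", 1 / config@effectFc, 1))
  S4Vectors::mcols(truth)$recurring_pairs <- methods::as(
    lapply(seq_len(nLoci), function(i)
      if (direction[i] == "none") character(0) else
        patients[recurring[i, ]]), "CharacterList")

  ## expected fragment counts: loci x samples, per mark
  w <- GenomicRanges::width(loci)
  baseCount <- config@baseRpkmMean * (w / 1000) *
    (config@librarySize / 1e6)
  sampleIds <- c(rbind(paste0(patients, "_native"),
                       paste0(patients, "_tumor")))
  tissueOf <- rep(c("native", "tumor"), nPairs)
  patientOf <- rep(patients, each = 2L)
  mult <- matrix(1, nLoci, 2L * nPairs, dimnames = list(NULL, sampleIds))
  mult[isSe, ] <- config@seSignalBoost
  for (j in seq_len(nPairs)) {
    tumorCol <- 2L * j; nativeCol <- 2L * j - 1L
    rec <- recurring[, j]
    mult[direction == "gain" & rec, tumorCol] <-
      mult[direction == "gain" & rec, tumorCol] * config@effectFc
    mult[direction == "lost" & rec, nativeCol] <-
      mult[direction == "lost" & rec, nativeCol] * config@effectFc
    ## sporadic background perturbations at unplanted loci
    bg <- direction == "none" &
      stats::runif(nLoci) < config@backgroundVariantRate
    up <- stats::runif(nLoci) < 0.5
    mult[bg & up, tumorCol] <- mult[bg & up, tumorCol] * config@effectFc
    mult[bg & !up, nativeCol] <- mult[bg & !up, nativeCol] *
      config@effectFc
  }
  muAc <- baseCount * mult
  muMe3 <- baseCount * ifelse(isM3e, config@m3eMe3Ratio, 1) * mult

  tssAll <- geneTSS(model)
  promAc <- if (length(tssAll)) GenomicRanges::GRanges(
    GenomicRanges::seqnames(tssAll),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(tssAll) - 500L),
                     GenomicRanges::start(tssAll) + 500L)) else
    GenomicRanges::GRanges()

  peakSets <- list(); fragmentSets <- list()
  for (s in seq_along(sampleIds)) {
    id <- sampleIds[s]
    acPeaks <- .sortGR(c(.jitterLoci(loci, config@peakJitter),
                         .jitterLoci(promAc, config@peakJitter / 2)))
    me3Peaks <- .sortGR(c(
      .jitterLoci(loci[isM3e], config@peakJitter),
      .jitterLoci(promAc, config@peakJitter / 2)))
    acCounts <- .nbDraw(nLoci, muAc[, s], config@nbDispersion)
    me3Counts <- .nbDraw(nLoci, muMe3[, s], config@nbDispersion)
    peakSets[[id]] <- list(
      H3K27ac = PeakSet(id, "H3K27ac", acPeaks),
      H3K4me3 = PeakSet(id, "H3K4me3", me3Peaks))
    fragmentSets[[id]] <- list(
      H3K27ac = FragmentSet(id, "H3K27ac",
        .fragmentsFromCounts(loci, acCounts, config@fragmentLengthBp),
        config@librarySize),
      H3K4me3 = FragmentSet(id, "H3K4me3",
        .fragmentsFromCounts(loci, me3Counts, config@fragmentLengthBp),
        config@librarySize))
  }

  pairs <- data.frame(patient_id = patients,
                      native = paste0(patients, "_native"),
                      tumor = paste0(patients, "_tumor"),
                      stringsAsFactors = FALSE)
  manifest <- do.call(rbind, lapply(seq_along(sampleIds), function(s)
    data.frame(patient_id = patientOf[s], tissue = tissueOf[s],
               mark = c("H3K27ac", "H3K4me3"),
               peak_path = NA_character_, fragment_path = NA_character_,
               total_mapped = config@librarySize,
               stringsAsFactors = FALSE)))

  bundle <- list(config = config, geneModel = model, masterLoci = loci,
                 truth = truth, peakSets = peakSets,
                 fragmentSets = fragmentSets, pairs = pairs,
                 manifest = manifest)
  if (!is.null(dir)) bundle <- .writeBundle(bundle, dir)
  bundle
}

.writeBundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeGtf(bundle$geneModel, file.path(dir, "genes.gtf"))
  mf <- bundle$manifest
  for (i in seq_len(nrow(mf))) {
    id <- paste0(mf$patient_id[i], "_", mf$tissue[i])
    mk <- mf$mark[i]
    pp <- sprintf("peaks_%s_%s.bed", id, mk)
    fp <- sprintf("fragments_%s_%s.bed", id, mk)
    writeLoci(peaks(bundle$peakSets[[id]][[mk]]), file.path(dir, pp),
              format = "bed")
    writeLoci(fragments(bundle$fragmentSets[[id]][[mk]]),
              file.path(dir, fp), format = "bed")
    mf$peak_path[i] <- pp
    mf$fragment_path[i] <- fp
  }
  utils::write.table(mf, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- bundle$truth
  df <- data.frame(
    locus_id = S4Vectors::mcols(tr)$locus_id,
    chrom = as.character(GenomicRanges::seqnames(tr)),
    start = GenomicRanges::start(tr) - 1L,
    end = GenomicRanges::end(tr),
    class = S4Vectors::mcols(tr)$class,
    direction = S4Vectors::mcols(tr)$direction,
    true_fc = S4Vectors::mcols(tr)$true_fc,
    recurring_pairs = vapply(S4Vectors::mcols(tr)$recurring_pairs,
                             paste, character(1), collapse = ","))
  utils::write.table(df, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bundle$manifest <- mf
  bundle$dir <- dir
  bundle
}

#' Score called variant loci against planted truth
#'
#' A planted locus is recovered iff at least one called locus of matching
#' class and direction overlaps it by \code{minOverlap} bases; a call is
#' matched iff it overlaps such a planted locus. Sensitivity is
#' recovered/planted; precision is matched/called, reported as 1 (and
#' flagged) when there are no calls at all.
#'
#' @param called \code{GRanges} with \code{class} and \code{direction}
#'   metadata (as returned by the variant callers).
#' @param truth the \code{truth} element of [generateCohort()]'s result.
#' @param classMatch named map from called class to planted truth class.
#' @param minOverlap minimum overlap in bases.
#' @return List with \code{sensitivity}, \code{precision},
#'   \code{nCalls}, \code{zeroCalls} and a per-(class, direction)
#'   \code{confusion} data frame.
#' @export
scoreRecovery <- function(called, truth,
                          classMatch = c(Vm3E = "m3E", VEL = "m3E",
                                         VSEL = "SE"),
                          minOverlap = 1L) {
  dirT <- S4Vectors::mcols(truth)$direction
  planted <- truth[dirT %in% VARIANT_DIRECTIONS]
  calledCls <- unique(S4Vectors::mcols(called)$class)
  if (length(called) && !all(calledCls %in% names(classMatch)))
    stop("called classes not covered by 'classMatch': ",
         paste(setdiff(calledCls, names(classMatch)), collapse = ", "))
  combos <- expand.grid(class = if (length(called)) calledCls else
    names(classMatch), direction = VARIANT_DIRECTIONS,
    stringsAsFactors = FALSE)
  conf <- list(); recovered <- 0L; matched <- 0L
  for (i in seq_len(nrow(combos))) {
    cl <- combos$class[i]; d <- combos$direction[i]
    tSub <- planted[S4Vectors::mcols(planted)$class == classMatch[[cl]] &
                      S4Vectors::mcols(planted)$direction == d]
    cSub <- called[S4Vectors::mcols(called)$class == cl &
                     S4Vectors::mcols(called)$direction == d]
    rec <- sum(IRanges::overlapsAny(tSub, cSub, minoverlap = minOverlap,
                                    ignore.strand = TRUE))
    mat <- sum(IRanges::overlapsAny(cSub, tSub, minoverlap = minOverlap,
                                    ignore.strand = TRUE))
    recovered <- recovered + rec; matched <- matched + mat
    conf[[i]] <- data.frame(class = cl, direction = d,
                            planted = length(tSub), recovered = rec,
                            calls = length(cSub), matched = mat)
  }
  conf <- do.call(rbind, conf)
  nPlanted <- sum(conf$planted)
  zero <- length(called) == 0L
  if (zero) warning("no called loci: precision reported as 1 by ",
                    "convention")
  list(sensitivity = if (nPlanted) recovered / nPlanted else NA_real_,
       precision = if (zero) 1 else matched / length(called),
       nCalls = length(called), zeroCalls = zero, confusion = conf)
}
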