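## Shared fixtures. Coordinates in tests are written 0-based half-open
## (file convention) and converted here to the 1-based GRanges kept
## in memory.

gr0 <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0))
}

## random interval set on a small genome (call inside withr::with_seed)
randGR <- function(n, chroms = c("chr1", "chr2"), maxPos = 1e5,
                   maxWidth = 500) {
  s <- sample.int(maxPos, n, replace = TRUE)
  w <- sample.int(maxWidth, n, replace = TRUE)
  GenomicRanges::GRanges(sample(chroms, n, replace = TRUE),
                         IRanges::IRanges(s, width = w))
}

## one '+' gene per TSS position (0-based), for distance tests
tssModel <- function(tssPos0, chrom = "chr1", geneLen = 1000L) {
  g <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(tssPos0 + 1L, width = geneLen), strand = "+")
  names(g) <- sprintf("g%03d", seq_along(g))
  GeneModel(g)
}

## cohort cache: default-condition cohorts are expensive, share them
## across test files
.cohorts <- new.env(parent = emptyenv())

cachedCohort <- function(seed, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.cohorts[[key]]))
    .cohorts[[key]] <- suppressWarnings(
      generateCohort(simConfig(seed = seed, ...)))
  .cohorts[[key]]
}

## enhancer/m3E calling over a whole cohort (cached alongside)
cohortEnhancers <- function(coh) {
  key <- paste0("enh|", coh$config@seed, "|",
                paste(deparse(coh$config), collapse = ""))
  if (is.null(.cohorts[[key]])) {
    gm <- coh$geneModel
    sets <- lapply(names(coh$peakSets), function(id)
      callM3Es(callActiveEnhancers(coh$peakSets[[id]]$H3K27ac, gm),
               coh$peakSets[[id]]$H3K4me3, gm))
    names(sets) <- names(coh$peakSets)
    .cohorts[[key]] <- sets
  }
  .cohorts[[key]]
}

cohortM3eLoci <- function(coh) {
  sets <- cohortEnhancers(coh)
  lapply(sets, function(es) {
    e <- enhancers(es)
    e[S4Vectors::mcols(e)$class == "m3E"]
  })
}

cohortAcFrags <- function(coh) lapply(coh$fragmentSets, `[[`, "H3K27ac")

cohortVm3es <- function(coh) {
  key <- paste0("vm3e|", coh$config@seed, "|",
                paste(deparse(coh$config), collapse = ""))
  if (is.null(.cohorts[[key]]))
    .cohorts[[key]] <- suppressWarnings(
      callVm3Es(cohortM3eLoci(coh), cohortAcFrags(coh), coh$pairs))
  .cohorts[[key]]
}

## small bundle on disk for pipeline tests
smallSimConfig <- function(seed = 7) {
  simConfig(seed = seed, nPairs = 6, nEnhancersPerSample = 120,
            nGainVm3e = 12, nLostVm3e = 5, nGenes = 60, nSeClusters = 2,
            nChroms = 2, chromLengthBp = 8e6)
}
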