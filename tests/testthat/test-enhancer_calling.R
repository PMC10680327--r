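test_that("the distal filter keeps only peaks beyond the TSS exclusion", {
  gm <- tssModel(10000)
  pk <- PeakSet("s", "H3K27ac",
                c(gr0("chr1", 12500, 13000),   # distance 2500: kept
                  gr0("chr1", 11000, 11500)))  # distance 1000: dropped
  es <- callActiveEnhancers(pk, gm)
  expect_equal(length(es), 1L)
  expect_equal(GenomicRanges::start(enhancers(es)) - 1L, 12500L)
  expect_equal(S4Vectors::mcols(enhancers(es))$class, "TE")

  empty <- callActiveEnhancers(PeakSet("s", "H3K27ac",
                                       GenomicRanges::GRanges()), gm)
  expect_equal(length(empty), 0L)
})

test_that("the distal filter equals a brute-force filter and is assertable post hoc", {
  withr::with_seed(21, {
    pk <- PeakSet("s", "H3K27ac", randGR(100, maxPos = 2e5))
    tpos <- sample.int(2e5, 20)
    tchrom <- sample(c("chr1", "chr2"), 20, replace = TRUE)
    g <- GenomicRanges::GRanges(tchrom,
                                IRanges::IRanges(tpos + 1L, width = 500L),
                                strand = "+")
    names(g) <- sprintf("g%02d", 1:20)
    gm <- GeneModel(g)
    es <- callActiveEnhancers(pk, gm)
    keepWant <- vapply(seq_along(peaks(pk)), function(i) oracleMinDist(
      as.character(GenomicRanges::seqnames(peaks(pk)))[i],
      GenomicRanges::start(peaks(pk))[i] - 1,
      GenomicRanges::end(peaks(pk))[i], tchrom, tpos) > 2000,
      logical(1))
    expect_equal(length(es), sum(keepWant))
    expect_true(all(minDistanceToTSS(enhancers(es), gm)$distance > 2000))
  })
})

test_that("m3E classification requires a TSS-distal H3K4me3 peak", {
  gm <- tssModel(0)  # TSS far to the left of everything below
  enh <- callActiveEnhancers(
    PeakSet("s", "H3K27ac", gr0("chr1", 5000, 6000)), gm)
  ## distal H3K4me3 overlap: enhancer becomes m3E, keeping its coordinates
  m1 <- callM3Es(enh, PeakSet("s", "H3K4me3", gr0("chr1", 5500, 7000)), gm)
  expect_equal(S4Vectors::mcols(enhancers(m1))$class, "m3E")
  expect_equal(GenomicRanges::start(enhancers(m1)) - 1L, 5000L)

  ## an H3K4me3 peak within 2 kb of a TSS is ignored: the enhancer
  ## [1000,2000) is distal to TSS 6500 (distance 4501) but the peak
  ## [1500,5500) is promoter-proximal (distance 1001)
  gmNear <- tssModel(6500)
  enh2 <- callActiveEnhancers(
    PeakSet("s", "H3K27ac", gr0("chr1", 1000, 2000)), gmNear)
  m3 <- callM3Es(enh2, PeakSet("s", "H3K4me3", gr0("chr1", 1500, 5500)),
                 gmNear)
  expect_equal(S4Vectors::mcols(enhancers(m3))$class, "TE")
  expect_equal(length(m3@metadata$h3k4me3Distal), 0L)

  ## no H3K4me3 peaks at all: zero m3Es
  m4 <- callM3Es(enh, PeakSet("s", "H3K4me3", GenomicRanges::GRanges()),
                 gm)
  expect_true(all(S4Vectors::mcols(enhancers(m4))$class == "TE"))
})

test_that("m3Es are always a subset of the called enhancers", {
  coh <- cachedCohort(101)
  es <- cohortEnhancers(coh)[[1]]
  enh <- enhancers(es)
  m3e <- enh[S4Vectors::mcols(enh)$class == "m3E"]
  expect_true(all(IRanges::overlapsAny(m3e, enh, type = "equal")))
  expect_true(all(minDistanceToTSS(enh, coh$geneModel)$distance > 2000))
})

test_that("super-enhancer calling follows the tangent rule", {
  gm <- tssModel(0)
  ## five isolated candidates with signals 1,1,1,1,40: only the 40 is SE
  pos <- seq(50000, by = 40000, length.out = 5)
  enh <- GenomicRanges::GRanges("chr1", IRanges::IRanges(pos, width = 1000))
  S4Vectors::mcols(enh)$class <- rep("TE", 5)
  es <- EnhancerSet("s", enh)
  se <- stitchSuperEnhancers(es, c(1, 1, 1, 1, 40))
  expect_equal(length(se), 1L)
  expect_equal(GenomicRanges::start(se), pos[5])
  expect_equal(S4Vectors::mcols(se)$totalSignal, 40)

  ## a flat curve yields no super enhancers
  expect_equal(length(stitchSuperEnhancers(es, rep(3, 5))), 0L)

  ## fewer than 3 candidates: warning, none called
  expect_warning(
    none <- stitchSuperEnhancers(EnhancerSet("s", enh[1:2]), c(1, 2)),
    "fewer than 3")
  expect_equal(length(none), 0L)
})

test_that("stitching merges enhancers within the stitch distance only", {
  close2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(10000, 16000), width = 1000))  # 5 kb apart
  far2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(100000, 121000), width = 1000))  # 20 kb apart
  expect_equal(length(mergeIntervals(close2, gap = 12500)), 1L)
  expect_equal(length(mergeIntervals(far2, gap = 12500)), 2L)

  ## the stitched pair with dominant signal is called as one SE envelope
  filler <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(3e5, by = 50000, length.out = 4), width = 1000))
  enh <- c(close2, filler)
  S4Vectors::mcols(enh)$class <- rep("TE", length(enh))
  se <- stitchSuperEnhancers(EnhancerSet("s", enh),
                             c(30, 30, 1, 1, 1, 1))
  expect_equal(length(se), 1L)
  expect_equal(GenomicRanges::width(se), 7000L)
  expect_equal(S4Vectors::mcols(se)$nConstituents, 2L)
})

test_that("genomic distribution partitions loci with the stated priority", {
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 110000),
                              strand = "+")
  names(g) <- "gA"
  ex <- methods::as(GenomicRanges::GRangesList(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100001, 108001), c(101000, 110000)))),
    "GRangesList")
  gm <- GeneModel(g, ex)
  loci <- suppressWarnings(
    c(gr0("chr1", 100100, 100200),   # promoter (and exon): promoter
      gr0("chr1", 108500, 108600),   # exon
      gr0("chr1", 105000, 105400),   # intron
      gr0("chr2", 5000, 5400)))      # intergenic
  got <- annotateGenomicDistribution(loci, gm)
  expect_equal(unname(got), c(1L, 1L, 1L, 1L))
  expect_equal(sum(got), length(loci))

  withr::with_seed(77, {
    x <- randGR(200, maxPos = 3e5)
    expect_equal(sum(annotateGenomicDistribution(x, gm)), length(x))
  })
})

test_that("QC excludes low-count samples together with their pair partner", {
  d <- withr::local_tempdir()
  mkbed <- function(name, n) {
    s <- seq(1000, by = 2000, length.out = n)
    writeLines(sprintf("chr1\t%d\t%d", s, s + 500), file.path(d, name))
    name
  }
  pts <- c("A", "B")
  rows <- list()
  counts <- c(A_native = 60, A_tumor = 58, B_native = 4, B_tumor = 56)
  for (p in pts) for (ti in c("native", "tumor")) {
    nm <- mkbed(sprintf("%s_%s.bed", p, ti),
                counts[[paste0(p, "_", ti)]])
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = p, tissue = ti, mark = "H3K27ac",
      peak_path = file.path(d, nm), fragment_path = NA,
      total_mapped = 1e6)
  }
  mf <- do.call(rbind, rows)
  rep <- qcFilterSamples(mf, minPeaks = 50)
  expect_equal(rep$included, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(rep$reason[3], "low peak count")
  expect_equal(rep$reason[4], "pair partner excluded")

  rep2 <- qcFilterSamples(mf, minPeaks = 2)
  expect_true(all(rep2$included))
})
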