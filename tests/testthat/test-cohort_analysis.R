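test_that("fraction report computes both ratios and flags empty samples", {
  withr::with_seed(41, {
    enh <- randGR(600, maxPos = 1e6)
    S4Vectors::mcols(enh)$class <- rep(c("m3E", "TE"), c(60, 540))
  })
  es <- EnhancerSet("s1", enh)
  m3e <- enh[S4Vectors::mcols(enh)$class == "m3E"]
  pkAll <- PeakSet("s1", "H3K4me3", c(m3e[1:30], randGR(70, maxPos = 1e7)))
  fr <- fractionReport(list(s1 = es), list(s1 = pkAll))
  expect_equal(fr$m3e_fraction, 0.1)
  expect_equal(fr$n_h3k4me3_peaks, 100L)
  expect_true(fr$h3k4me3_fraction_on_m3e >= 0.3)
  expect_false(fr$flagged)

  none <- EnhancerSet("s2", enh[0])
  fr2 <- fractionReport(list(s2 = none), list(s2 = pkAll))
  expect_true(is.na(fr2$m3e_fraction))
  expect_true(fr2$flagged)

  S4Vectors::mcols(enh)$class <- rep("TE", length(enh))
  fr3 <- fractionReport(list(s3 = EnhancerSet("s3", enh)),
                        list(s3 = pkAll))
  expect_equal(fr3$m3e_fraction, 0)
})

test_that("target genes are the k nearest TSS with lexicographic ties", {
  g <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(110001, 150001), width = 5000), strand = "+")
  names(g) <- c("geneA", "geneB")
  gm <- GeneModel(g)
  ## locus at 100000: geneA 10 kb away, geneB 50 kb away
  loc <- gr0("chr1", 99000, 100000)
  expect_equal(as.list(assignTargetGenes(loc, gm))[[1]], "geneA")
  expect_equal(as.list(assignTargetGenes(loc, gm, kNearest = 2))[[1]],
               c("geneA", "geneB"))

  ## equidistant genes: lexicographic tie-break
  g2 <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(90001, 110001), width = 100), strand = "+")
  names(g2) <- c("geneB", "geneA")
  loc2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 100001))
  expect_equal(as.list(assignTargetGenes(loc2, GeneModel(g2)))[[1]],
               "geneA")

  ## nothing in range
  far <- gr0("chr1", 5e6, 5e6 + 100)
  expect_equal(lengths(assignTargetGenes(far, gm, maxDistanceBp = 1e5)),
               0L)
})

test_that("target assignment equals the brute-force nearest scan", {
  withr::with_seed(42, {
    tpos <- sample.int(5e5, 40)
    tchrom <- sample(c("chr1", "chr2"), 40, replace = TRUE)
    g <- GenomicRanges::GRanges(tchrom,
      IRanges::IRanges(tpos + 1L, width = 200L), strand = "+")
    names(g) <- sprintf("g%02d", 1:40)
    gm <- GeneModel(g)
    loci <- randGR(100, maxPos = 5e5)
    got <- as.list(assignTargetGenes(loci, gm, maxDistanceBp = 5e4))
    for (i in seq_along(loci)) {
      d <- vapply(1:40, function(j) oracleMinDist(
        as.character(GenomicRanges::seqnames(loci))[i],
        GenomicRanges::start(loci)[i] - 1, GenomicRanges::end(loci)[i],
        tchrom[j], tpos[j]), numeric(1))
      inRange <- which(d <= 5e4)
      want <- if (length(inRange))
        names(g)[inRange[order(d[inRange], names(g)[inRange])]][1] else
        character(0)
      expect_identical(got[[i]], want)
    }
  })
})

test_that("expression comparison uses the exact rank-sum for small groups", {
  expr <- stats::setNames(c(1, 2, 3, 4, 5, 6),
                          c("a1", "a2", "a3", "b1", "b2", "b3"))
  out <- compareTargetExpression(
    list(TE = c("a1", "a2", "a3"), m3E = c("b1", "b2", "b3")), expr)
  expect_equal(out$summaries$median, c(2, 5))
  expect_equal(out$tests$p,
               oracleRankSumP(c(1, 2, 3), c(4, 5, 6)))

  same <- compareTargetExpression(
    list(g1 = c("a1", "a2", "a3"), g2 = c("a1", "a2", "a3")), expr)
  expect_gte(same$tests$p, 0.99)

  ## genes missing from the table are dropped and counted
  out2 <- compareTargetExpression(
    list(TE = c("a1", "zz"), m3E = c("b1", "b2")), expr)
  expect_equal(out2$summaries$n_dropped, c(1L, 0L))
})

test_that("a generated SE > m3E > TE expression ordering is recovered", {
  hits <- 0L
  withr::with_seed(43, {
    for (r in 1:20) {
      expr <- c(rlnorm(30, 0, 0.5), rlnorm(30, 0.7, 0.5),
                rlnorm(30, 1.4, 0.5))
      names(expr) <- sprintf("g%02d", 1:90)
      out <- compareTargetExpression(
        list(TE = names(expr)[1:30], m3E = names(expr)[31:60],
             SE = names(expr)[61:90]), expr)
      md <- out$summaries$median
      if (md[1] < md[2] && md[2] < md[3]) hits <- hits + 1L
    }
  })
  expect_gte(hits, 19L)
})

test_that("PCA separates duplicated sample groups and matches an SVD oracle", {
  loci <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 2000, length.out = 10), width = 1000))
  base <- matrix(5, nrow = 10, ncol = 6)
  base[1, 4:6] <- 50    # one locus separates the two triplets
  cd <- S4Vectors::DataFrame(
    sample_id = paste0("s", 1:6),
    tissue = rep(c("native", "tumor"), each = 3),
    row.names = paste0("s", 1:6))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = base), rowRanges = loci, colData = cd)
  pc <- pcaClassification(se)
  expect_true(max(pc$PC1[1:3]) < min(pc$PC1[4:6]) ||
                max(pc$PC1[4:6]) < min(pc$PC1[1:3]))
  expect_equal(pc$PC2, rep(0, 6), tolerance = 1e-9)

  withr::with_seed(44, mat <- matrix(rexp(60), nrow = 10))
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = mat), rowRanges = loci, colData = cd)
  pc2 <- pcaClassification(se2)
  ## independent oracle: svd of the centered log matrix
  m <- t(log2(mat + 1)); m <- sweep(m, 2, colMeans(m))
  sv <- svd(m)
  for (j in 1:2) {
    want <- sv$u[, j] * sv$d[j]
    got <- pc2[[paste0("PC", j)]]
    expect_equal(abs(got), abs(want), tolerance = 1e-9)
  }
  ## reordering samples permutes coordinates only
  perm <- c(4, 2, 6, 1, 3, 5)
  se3 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = mat[, perm]), rowRanges = loci,
    colData = cd[perm, ])
  pc3 <- pcaClassification(se3)
  expect_equal(pc3$PC1, pc2$PC1[perm], tolerance = 1e-9)

  seConst <- SummarizedExperiment::SummarizedExperiment(
    assays = list(rpkm = matrix(3, 10, 6)), rowRanges = loci,
    colData = cd)
  expect_warning(pcC <- pcaClassification(seConst), "constant")
  expect_equal(pcC$PC1, rep(0, 6))
})

test_that("TF overlap fractions track planted occupancy exactly", {
  withr::with_seed(45, {
    tps <- paste0("wk", c(0, 2, 4, 7))
    target <- c(0.2, 0.4, 0.6, 0.8)
    m3eSets <- list(); tf <- GenomicRanges::GRanges()
    for (i in seq_along(tps)) {
      m <- randGR(200, chroms = paste0("chr", i), maxPos = 1e6)
      m3eSets[[tps[i]]] <- m
      bound <- sample(200, round(target[i] * 200))
      tf <- suppressWarnings(c(tf, GenomicRanges::granges(m[bound])))
    }
    enhSets <- m3eSets
  })
  out <- tfOverlapTrend(m3eSets, enhSets, tf)
  expect_equal(out$m3e_tf_fraction, target, tolerance = 0.05)
  expect_true(all(diff(out$m3e_tf_fraction) > 0))

  out0 <- tfOverlapTrend(m3eSets, enhSets, GenomicRanges::GRanges())
  expect_equal(out0$m3e_tf_fraction, rep(0, 4))

  outE <- tfOverlapTrend(list(t1 = GenomicRanges::GRanges()),
                         list(t1 = GenomicRanges::GRanges()), tf)
  expect_true(is.na(outE$m3e_tf_fraction))
  expect_true(outE$flagged)
})

test_that("eight of ten m3Es bound gives fraction 0.8", {
  m <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 5000, length.out = 10), width = 1000))
  tf <- GenomicRanges::granges(m[1:8])
  out <- tfOverlapTrend(list(t1 = m), list(t1 = m), tf)
  expect_equal(out$m3e_tf_fraction, 0.8)
})
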