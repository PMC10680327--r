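test_that("per-pair variant calls respect the inclusive FC threshold", {
  loci <- c(gr0("chr1", 0, 1000), gr0("chr1", 2000, 3000),
            gr0("chr1", 4000, 5000))
  out <- callPairwiseVariants(loci, tumorRpkm = c(20, 10, 5),
                              nativeRpkm = c(10, 10, 20),
                              fcThreshold = 2, pseudocount = 0)
  expect_equal(length(out), 2L)
  expect_equal(S4Vectors::mcols(out)$direction, c("gain", "lost"))
  expect_equal(S4Vectors::mcols(out)$fc, c(2, 0.25))

  expect_error(callPairwiseVariants(loci, 1:3, 1:3, fcThreshold = 1),
               "exceed 1")
})

test_that("raising the FC threshold never increases per-pair calls", {
  withr::with_seed(31, {
    loci <- randGR(200)
    t <- runif(200, 0, 30); nat <- runif(200, 0, 30)
    sizes <- vapply(c(1.5, 2, 3, 5), function(th)
      length(callPairwiseVariants(loci, t, nat, th)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("cohort merging stratifies by direction and counts patients", {
  g1 <- gr0("chr1", 100, 200); g2 <- gr0("chr1", 150, 260)
  S4Vectors::mcols(g1)$direction <- "gain"
  S4Vectors::mcols(g2)$direction <- "gain"
  m <- mergeCohortVariants(list(p1 = g1, p2 = g2), nPairs = 2)
  expect_equal(length(m), 1L)
  expect_equal(GenomicRanges::start(m) - 1L, 100L)
  expect_equal(GenomicRanges::end(m), 260L)
  expect_equal(S4Vectors::mcols(m)$recurrence, 2L)

  ## opposite directions stay separate
  S4Vectors::mcols(g2)$direction <- "lost"
  m2 <- mergeCohortVariants(list(p1 = g1, p2 = g2), nPairs = 2)
  expect_equal(length(m2), 2L)
  expect_equal(sort(S4Vectors::mcols(m2)$recurrence), c(1L, 1L))

  ## two overlapping calls from one patient count once
  both <- c(g1, gr0("chr1", 180, 250))
  S4Vectors::mcols(both)$direction <- "gain"
  m3 <- mergeCohortVariants(list(p1 = both), nPairs = 3)
  expect_equal(S4Vectors::mcols(m3)$recurrence, 1L)
})

test_that("the binomial recurrence tail is exact", {
  expect_equal(recurrencePvalue(1, 1, 0.5), 0.5)
  expect_equal(recurrencePvalue(3, 3, 0.5), 0.125)
  for (n in c(3, 7, 12)) for (p0 in c(0.02, 0.2, 0.6)) for (k in 1:n)
    expect_equal(recurrencePvalue(k, n, p0), oracleBinomTail(k, n, p0),
                 tolerance = 1e-12)
  ## monotone: decreasing in k, increasing in p0
  pv <- recurrencePvalue(1:10, 10, 0.1)
  expect_true(all(diff(pv) < 0))
  expect_lt(recurrencePvalue(5, 10, 0.1), recurrencePvalue(5, 10, 0.3))
  expect_error(recurrencePvalue(5, 10, 0), "p0")
  expect_error(recurrencePvalue(11, 10, 0.1), "1 <= k <= n")
})

test_that("the null rate is the clamped call ratio", {
  expect_equal(estimateNull(rep(20, 10), rep(1000, 10))$p0, 0.02)
  expect_equal(estimateNull(0, 10000)$p0, 1e-4)
  expect_equal(estimateNull(10000, 10000)$p0, 1 - 1e-4)
  expect_error(estimateNull(0, 0), "zero tested")
})

test_that("the generator's background variant rate is recovered by estimateNull", {
  ests <- vapply(1:10, function(s) {
    coh <- cachedCohort(400 + s, nPairs = 4, nChroms = 2,
                        chromLengthBp = 6e6, nGenes = 40,
                        nEnhancersPerSample = 150, nGainVm3e = 0,
                        nLostVm3e = 0, nSeClusters = 0,
                        nbDispersion = 0.001, baseRpkmMean = 300,
                        backgroundVariantRate = 0.02)
    loci <- GenomicRanges::granges(coh$masterLoci)
    lociBy <- stats::setNames(
      rep(list(loci), 2 * nrow(coh$pairs)),
      c(rbind(coh$pairs$native, coh$pairs$tumor)))
    ps <- buildPairSignals(lociBy, cohortAcFrags(coh), coh$pairs)
    calls <- vapply(ps, function(x) length(
      callPairwiseVariants(x$loci, x$tumor, x$native)), integer(1))
    estimateNull(calls, vapply(ps, function(x) length(x$loci),
                               integer(1)))$p0
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.02), 0.005)
})

test_that("BH adjustment matches the reference step-up and validates input", {
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(32, {
    for (r in 1:50) {
      p <- pmax(runif(sample.int(40, 1)), 1e-12)
      expect_equal(bhAdjust(p), oracleBH(p), tolerance = 1e-12)
    }
  })
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("recurrence-threshold selection implements the significant-percentage rule", {
  ## constructed strata: fractions 0.63 / 0.76 / 0.825 / 0.96 at r=5..8
  rec <- rep(c(5L, 6L, 7L, 8L), c(10, 10, 15, 25))
  q <- c(rep(0.5, 10),
         rep(c(0.01, 0.5), c(5, 5)),
         rep(c(0.01, 0.5), c(9, 6)),
         rep(c(0.01, 0.5), c(24, 1)))
  expect_equal(selectRecurrenceThreshold(rec, q), 8L)

  ## every locus significant: the minimum observed recurrence wins
  expect_equal(selectRecurrenceThreshold(c(4L, 6L, 9L), rep(0.001, 3)),
               4L)

  ## nothing reaches the cutoff
  expect_warning(r <- selectRecurrenceThreshold(rec, rep(0.5, 60)),
                 "no recurrence threshold")
  expect_true(is.na(r))
  expect_error(selectRecurrenceThreshold(integer(0), numeric(0)),
               "empty")

  withr::with_seed(33, {
    rec2 <- sample(1:20, 200, replace = TRUE)
    ## significance enriched at high recurrence, as in real strata
    q2 <- runif(200) * (21 - rec2) / 20
    expect_equal(selectRecurrenceThreshold(rec2, q2, 0.6),
                 oracleThreshold(rec2, q2, frac = 0.6))
    ## raising the cutoff never lowers the threshold
    ths <- vapply(c(0.3, 0.5, 0.7), function(fc)
      selectRecurrenceThreshold(rec2, q2, fc), integer(1))
    expect_true(all(diff(ths) >= 0))
  })
})

test_that("callVELs guards degenerate cohorts", {
  one <- list(P1 = list(loci = gr0("chr1", 0, 1000), tumor = 10,
                        native = 1))
  expect_error(callVELs(one), "at least 3 pairs")

  flat <- lapply(1:4, function(i)
    list(loci = gr0("chr1", 0, 1000), tumor = 10, native = 10))
  names(flat) <- paste0("P", 1:4)
  expect_warning(v <- callVELs(flat), "no per-pair variant calls")
  expect_equal(length(v), 0L)
})

test_that("planted variant loci are recovered as VELs on the synthetic cohort", {
  coh <- cachedCohort(101)
  ps <- buildPairSignals(lapply(cohortEnhancers(coh), enhancers),
                         cohortAcFrags(coh), coh$pairs)
  vel <- suppressWarnings(callVELs(ps))
  sc <- scoreRecovery(vel, coh$truth, classMatch = c(VEL = "m3E"))
  expect_gte(sc$sensitivity, 0.9)
  expect_gte(sc$precision, 0.9)
  th <- S4Vectors::metadata(vel)$thresholds
  expect_true(all(th[c("gain", "lost")] >= 1))
  ## no merged locus carries both directions
  key <- paste(GenomicRanges::seqnames(vel), GenomicRanges::start(vel))
  expect_true(all(table(key) <= 2) &&
                !anyDuplicated(paste(key,
                                     S4Vectors::mcols(vel)$direction)))
})

test_that("Vm3E calling composes the per-pair and cohort-mean stages", {
  locus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 2000))
  mkFrag <- function(id, count) FragmentSet(id, "H3K27ac",
    GenomicRanges::GRanges("chr1",
      IRanges::IRanges(rep(1101, count), width = 200)), 1e6)
  m3e <- stats::setNames(rep(list(locus), 6),
                         c("P1_native", "P1_tumor", "P2_native",
                           "P2_tumor", "P3_native", "P3_tumor"))
  pairs <- data.frame(patient_id = c("P1", "P2", "P3"),
                      native = c("P1_native", "P2_native", "P3_native"),
                      tumor = c("P1_tumor", "P2_tumor", "P3_tumor"))
  ## cohort mean FC (7.833/3.833 = 2.04) and a stage-1 supporter: gain
  frags <- list(P1_native = mkFrag("P1_native", 2),
                P1_tumor = mkFrag("P1_tumor", 10),
                P2_native = mkFrag("P2_native", 4),
                P2_tumor = mkFrag("P2_tumor", 6),
                P3_native = mkFrag("P3_native", 4),
                P3_tumor = mkFrag("P3_tumor", 6))
  vm <- callVm3Es(m3e, frags, pairs)
  expect_equal(length(vm), 1L)
  expect_equal(S4Vectors::mcols(vm)$direction, "gain")
  expect_equal(S4Vectors::mcols(vm)$class, "Vm3E")
  expect_gte(S4Vectors::mcols(vm)$recurrence, 1L)

  ## cohort mean FC below 1.5 is not called even with stage-1 support
  frags2 <- frags
  frags2$P2_tumor <- mkFrag("P2_tumor", 3)
  frags2$P3_tumor <- mkFrag("P3_tumor", 3)
  frags2$P2_native <- mkFrag("P2_native", 5)
  frags2$P3_native <- mkFrag("P3_native", 5)
  expect_equal(length(callVm3Es(m3e, frags2, pairs)), 0L)
})

test_that("Vm3E recovery meets the planted sensitivity and precision", {
  coh <- cachedCohort(101)
  vm <- cohortVm3es(coh)
  sc <- scoreRecovery(vm, coh$truth)
  expect_gte(sc$sensitivity, 0.9)
  expect_gte(sc$precision, 0.9)
})

test_that("VSELs use the fixed recurrence threshold", {
  seA <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000))
  seB <- GenomicRanges::GRanges("chr1", IRanges::IRanges(50001, 60000))
  loci <- c(seA, seB)
  n <- 10
  ps <- lapply(1:n, function(i) {
    ## locus A gains in pairs 1-8, locus B in pairs 1-4 only
    list(loci = loci,
         tumor = c(if (i <= 8) 40 else 10, if (i <= 4) 40 else 10),
         native = c(10, 10))
  })
  names(ps) <- sprintf("P%02d", 1:n)
  vs <- callVSELs(ps, recurrenceThreshold = 5)
  expect_equal(length(vs), 1L)
  expect_equal(GenomicRanges::start(vs), 10001L)
  expect_equal(S4Vectors::mcols(vs)$recurrence, 8L)
  expect_equal(S4Vectors::mcols(vs)$class, "VSEL")

  empty <- lapply(1:3, function(i)
    list(loci = GenomicRanges::GRanges(), tumor = numeric(0),
         native = numeric(0)))
  names(empty) <- paste0("P", 1:3)
  expect_warning(v0 <- callVSELs(empty), "no per-pair")
  expect_equal(length(v0), 0L)
})

test_that("the permutation null agrees with the binomial null", {
  withr::with_seed(34, {
    m <- matrix(runif(300 * 8) < 0.25, nrow = 300)
  })
  pPerm <- recurrencePvaluePermutation(m, nPerm = 200, seed = 35)
  p0 <- mean(m)
  k <- rowSums(m)
  pBin <- ifelse(k == 0, 1, recurrencePvalue(pmax(k, 1), 8, p0))
  expect_lt(median(abs(pPerm - pBin)), 0.05)
})
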