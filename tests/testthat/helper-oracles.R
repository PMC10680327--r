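## Independent brute-force oracles, written against 0-based half-open
## tuples so they share no code (or convention) with the implementation.

## do [s1,e1) and [s2,e2) on chrom c1/c2 overlap by >= minbp bases?
oracleOverlap <- function(c1, s1, e1, c2, s2, e2, minbp = 1) {
  c1 == c2 && (min(e1, e2) - max(s1, s2)) >= minbp
}

## O(n log n) sweep merge of a data.frame(chrom, start0, end0) at a gap
oracleMerge <- function(df, gap = 0) {
  df <- df[order(df$chrom, df$start0, df$end0), , drop = FALSE]
  out <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is.null(cur) && r$chrom == cur$chrom &&
          r$start0 <= cur$end0 + gap) {
      cur$end0 <- max(cur$end0, r$end0)
    } else {
      if (!is.null(cur)) out[[length(out) + 1]] <- cur
      cur <- r
    }
  }
  if (!is.null(cur)) out[[length(out) + 1]] <- cur
  do.call(rbind, out)
}

## exhaustive min distance (0-based): 0 if TSS inside, coordinate
## difference to the nearest edge otherwise
oracleMinDist <- function(chrom, s0, e0, tssChrom, tssPos0) {
  best <- Inf
  for (j in seq_along(tssPos0)) {
    if (tssChrom[j] != chrom) next
    d <- if (tssPos0[j] >= s0 && tssPos0[j] < e0) 0 else
      if (tssPos0[j] < s0) s0 - tssPos0[j] else tssPos0[j] - (e0 - 1)
    best <- min(best, d)
  }
  best
}

## naive overlap-count scan
oracleCount <- function(chrom, s0, e0, fc, fs0, fe0, minbp = 1) {
  sum(vapply(seq_along(fc), function(j)
    oracleOverlap(chrom, s0, e0, fc[j], fs0[j], fe0[j], minbp),
    logical(1)))
}

## reference BH step-up written from the definition
oracleBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

## term-by-term binomial upper tail
oracleBinomTail <- function(k, n, p) {
  sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
             numeric(1)))
}

## exhaustive scan for the recurrence-threshold rule
oracleThreshold <- function(rec, q, frac = 0.9, qcut = 0.05) {
  for (r in min(rec):max(rec)) {
    idx <- rec >= r
    if (any(idx) && mean(q[idx] < qcut) >= frac) return(r)
  }
  NA_integer_
}

## exact two-sided rank-sum p by enumeration of all group assignments,
## replicating the doubled-tail convention of the exact test
oracleRankSumP <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  W <- sum(rank(pooled)[seq_len(nA)]) - nA * (nA + 1) / 2
  combs <- utils::combn(length(pooled), nA)
  Ws <- apply(combs, 2, function(idx)
    sum(rank(pooled)[idx]) - nA * (nA + 1) / 2)
  mu <- nA * length(b) / 2
  p <- if (W > mu) 2 * mean(Ws >= W) else 2 * mean(Ws <= W)
  min(1, p)
}
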