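---
title: "m3Escan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m3Escan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Active enhancers are conventionally mapped from H3K27ac ChIP-seq, but a
subset of them additionally carries H3K4me3 — a mark classically
associated with promoters. These H3K4me3-enriched enhancers (m3Es) have
distinct regulatory behaviour, and in paired tumor/normal cohorts the
interesting objects are the *variant* loci: enhancers whose H3K27ac
signal changes reproducibly between the two tissues of many patients.
m3Escan implements the full discovery chain for such cohorts:

1. **Active enhancers**: H3K27ac peaks whose every base lies more than
   2 kb from all transcription start sites (the whole-peak distal rule).
   The 2 kb exclusion removes promoter signal bleed; applying it to the
   whole peak rather than the summit is the stricter of the two
   readings, and the choice is exposed via the `tssExclusionBp`
   parameter and the distance machinery in `minDistanceToTSS()`.
2. **m3Es**: enhancers overlapping (>= 1 bp by default) at least one
   H3K4me3 peak that is itself TSS-distal. The enhancer keeps its own
   coordinates; the H3K4me3 peak only licenses the label.
3. **Super enhancers**: enhancers within 12.5 kb are stitched, stitched
   candidates are ranked by summed RPKM, both axes of the rank–signal
   curve are scaled to [0, 1], and candidates above the point where a
   slope-1 line is tangent to the curve (the minimiser of `y - x`) are
   super enhancers. The first-crossing variant of the rule (smallest
   rank whose discrete slope exceeds 1) behaves identically on clean
   curves but fires inside the noise bulk on realistic ones, which is
   why the tangent-point form is used. A flat curve yields no calls,
   and fewer than three candidates is treated as degenerate.
4. **Signal**: fragments overlapping a locus by >= 1 bp, normalised as
   RPKM = count / (locus kb × library millions). Counting fragments
   (not read midpoints) matches the interval containers the pipeline
   consumes; the overlap threshold is a parameter.
5. **Variant loci**: per patient pair, a locus is a gain when
   tumor/native fold change >= 2 (lost symmetric; pseudocount 0.5
   stabilises near-zero signal). Per-pair calls are merged
   direction-stratified across the cohort; the recurrence of a merged
   locus is the number of *patients* (not calls) contributing an
   overlapping same-direction call.

## The recurrence significance test

The cohort analysis needs "how often would k of n pairs call this locus
by chance". The test is not prescribed by convention, so the package
makes the simplest defensible choice and isolates it behind a swappable
null model:

* the per-pair null rate `p0` is estimated from the cohort itself as
  total calls / total tested loci (`estimateNull()`), clamped one event
  away from 0 and 1. In the direction-stratified callers the rate is
  estimated per direction — a pooled rate would roughly double `p0`
  for each one-sided stratum;
* the p-value is the exact binomial upper tail `P(X >= k)`,
  `X ~ Bin(n, p0)` (`recurrencePvalue()`);
* Benjamini–Hochberg correction is applied per direction across merged
  loci (`bhAdjust()`);
* an empirical alternative, `recurrencePvaluePermutation()`, shuffles
  each pair's calls across loci and pools the permuted recurrence
  counts; it is used as a cross-check in the test suite, never as the
  primary route.

VEL recurrence thresholds are then data-driven: the smallest integer r
such that at least 90% of loci with recurrence >= r have q < 0.05
(`selectRecurrenceThreshold()`; the >= / > boundary is a switch because
either reading of "larger than" is defensible). VSELs use a fixed
threshold of 5 instead. Variant m3Es compose two stages: per-pair
fold-change candidates (FC >= 2) and a cohort-level mean-RPKM fold
change (>= 1.5 for gain, <= 1/1.5 for lost); a final Vm3E needs both —
the cohort filter alone ignores per-patient support, the per-pair stage
alone is far too permissive. An optional recurrence filter on Vm3Es
exists (`minRecurrence`) but defaults to off, since the two-threshold
definition does not include one.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| `tssExclusionBp` | 2000 | distal rule, whole-peak distance in bp |
| `pairFc` / `velFc` | 2.0 | per-pair fold-change threshold (inclusive) |
| `cohortFc` | 1.5 | cohort mean-FC threshold for Vm3Es |
| `significantFractionCutoff` | 0.90 | VEL threshold-selection rule |
| `qCutoff` | 0.05 | BH significance level |
| `vselRecurrence` | 5 | fixed VSEL recurrence threshold |
| `stitchBp` | 12500 | super-enhancer stitching distance |
| `pseudocount` | 0.5 | fold-change stabiliser (0 allowed; Inf handled) |
| `minPeaks` | 5000 | QC minimum peak count per mark |

The QC minimum is a judgment call: samples are excluded when a peak
file is degenerate, and exclusion always removes the whole patient so
pairing is preserved.

## The synthetic cohort

`generateCohort()` emulates the statistical structure the calling rules
assume: a small genome (4 × 10 Mb, 200 genes with exons), 500
TSS-distal enhancer loci shared by all samples, 20 native/tumor pairs,
negative-binomial fragment counts (variance mu + 0.3 mu²) at a baseline
of 30 RPKM, per-sample peak-boundary jitter of ±10% of locus width, and
planted structure: 20% of loci are m3Es (each with an overlapping
distal H3K4me3 peak at twice the TE-level H3K4me3 signal), five
three-member clusters with 8× signal destined to become super
enhancers, and 50 gain plus 20 lost variant m3Es whose recurring pairs
(drawn independently at rate 0.8) carry a 4-fold (resp. 1/4) H3K27ac
effect. Unplanted locus/pair combinations are sporadically perturbed at
rate 0.02 to give the null-rate estimator something real to estimate.

Choices a reader may wonder about:

* the m3E fraction defaults to 0.20 rather than the ~0.10 seen in real
  tissue cohorts because 70 planted variant m3Es must fit inside the
  m3E set of 500 × fraction loci with room for non-variant m3Es; the
  fraction-recovery test plants 0.10 with proportionally fewer variants
  (25 + 10);
* singleton loci are placed >= 15 kb apart — beyond the stitch distance
  — so multi-constituent stitched candidates exist exactly where
  clusters are planted; merge logic across samples is still exercised
  by the boundary jitter;
* recurrence is independent Bernoulli per pair; correlated patient
  structure (subtypes, batch) is deliberately out of scope;
* fragments are placed uniformly inside their locus and libraries have
  a constant declared size, so RPKM differences are purely count-driven.

What passing these tests does **not** show about real data: no
mappability or GC structure, no copy-number confounding of fold
changes, no correlated noise between the two marks beyond the planted
multipliers, no peak-caller artefacts beyond boundary jitter, and a
genome orders of magnitude smaller than a real one. Recovery rates on
the simulation are a correctness check of the machinery, not a
performance claim for tissue cohorts.

## Numerical and degenerate-case choices

* All in-memory coordinates are 1-based closed (`GRanges`); BED-family
  files are 0-based half-open and converted at the boundary, GTF is
  1-based and kept. Abutting half-open intervals do not overlap, but
  they do merge at gap 0 (touching counts as mergeable, not as
  overlap).
* Interval-to-TSS distance is the coordinate difference to the nearest
  locus edge (0 when the TSS is inside) — a TSS one base outside a
  locus is at distance 1.
* The TSS of a gene is the 5' end of its longest transcript; GTF files
  rarely say which transcript anchored an annotation, and longest is
  the reproducible choice. Strand only orients which end is the TSS;
  distances ignore strand.
* Tie-breaks are always deterministic: coordinate order for the SE
  rank curve, (distance, gene id) for target-gene assignment, and the
  first index for `which`-style minimisations.
* `estimateNull()` clamps p0 into [1/total, 1 − 1/total]; a cohort
  with zero calls still yields a usable (tiny) rate.
* PCA uses log2(RPKM + 1), per-locus centering, no variance scaling,
  and fixes component signs so the largest-magnitude loading is
  positive; a constant matrix returns all-zero coordinates with a
  warning rather than an error.
* Rank-sum comparisons use the exact distribution when both groups have
  <= 8 members and the normal approximation above, keeping small-sample
  tests deterministic.
* Fewer than 3 pairs cannot support recurrence calling and is an error;
  a cohort with no per-pair calls returns an empty set with a warning.

## Problem sizes in the test suite

The suite runs entirely on generated data: brute-force oracle checks
use 100–1000 random instances per operation; cohort-scale checks use
the reference simulation above (20 pairs × 500 loci), five seeds for
recovery, twenty for PCA separation, and a 6-pair × 120-locus bundle
for end-to-end pipeline and determinism tests. These sizes keep the
whole suite within a few minutes on one CPU while leaving every rule
exercised at cohort scale.

## Known limitations

* The recurrence null treats pairs as exchangeable and loci as
  independent; clustered loci violate the second assumption mildly
  (merging reduces but does not remove it).
* Cohort fold changes are not copy-number corrected.
* The Vm3E caller reports binomial/BH significance for its recurrence
  but does not filter on it; with noisy cohorts a handful of
  null loci can pass the two fold-change thresholds (see the null
  cohort analysis in the test suite).
* Super-enhancer calling on very small candidate sets (< 3) is refused
  rather than attempted.
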