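# m3Escan

Discovery of **H3K4me3-enriched enhancers (m3Es)** and **recurrent
variant enhancer loci** from paired native/tumor histone ChIP-seq
cohorts.

Active enhancers are mapped from H3K27ac, but a subset also carries
H3K4me3 — a mark usually confined to promoters — and these m3Es behave
differently from typical enhancers (TEs) and super enhancers (SEs). In
a cohort of patients with paired native and tumor samples, the loci of
interest are those whose enhancer signal changes reproducibly between
the two tissues. m3Escan implements that analysis as a tested,
reusable R package for epigenomicists working with peak files
(BED/narrowPeak/broadPeak), fragment interval files and a GTF
annotation — plus a synthetic-cohort generator with planted ground
truth, so the whole pipeline is verifiable without any external data.

## The method

For each QC-passing sample (peak count ≥ 5000 per mark; exclusion drops
the whole patient so pairing is preserved):

* **enhancers** = H3K27ac peaks with min distance to every TSS
  > 2 kb (whole-peak rule);
* **m3Es** = enhancers overlapping a TSS-distal H3K4me3 peak;
* **super enhancers** = ROSE-style: stitch enhancers within 12.5 kb,
  rank candidates by summed RPKM, call those above the slope-1 tangent
  point of the scaled rank–signal curve.

Signal over a locus is RPKM = fragments / (kb × million mapped reads).
For variant calling with *n* patient pairs:

* a per-pair call is **gain** when FC = (tumor + 0.5)/(native + 0.5) ≥ 2
  (lost symmetric);
* calls merge across the cohort per direction; the **recurrence** k of a
  merged locus is the number of patients contributing an overlapping
  same-direction call;
* significance is the exact binomial tail P(X ≥ k), X ~ Bin(n, p₀),
  with p₀ estimated as total calls / total tested loci, BH-corrected per
  direction;
* **VELs** keep loci with recurrence at or above the smallest r at which
  ≥ 90% of loci with recurrence ≥ r have q < 0.05; **VSELs** (on SE
  loci) use a fixed recurrence threshold of 5;
* **Vm3Es** compose two stages on m3E loci: a per-pair FC ≥ 2 supporter
  and a cohort mean-RPKM FC ≥ 1.5 (gain) or ≤ 1/1.5 (lost).

Downstream summaries: per-sample m3E/enhancer fractions, genomic
distribution (promoter/exon/intron/intergenic), nearest-TSS target-gene
assignment, rank-sum comparison of target expression across classes,
PCA classification of samples over variant loci, and TF-overlap trends.
See `vignette("m3Escan-methods")` for the model, parameter rationale and
design notes.

## Worked example

Simulate a 10-pair cohort with 30 gain and 10 lost planted variant
m3Es, run the calling chain, and score the calls against the planted
truth:

```r
library(m3Escan)

cfg <- simConfig(seed = 42, nPairs = 10, nEnhancersPerSample = 300,
                 nGainVm3e = 30, nLostVm3e = 10, nGenes = 120)
cohort <- generateCohort(cfg)

gm <- cohort$geneModel
enhSets <- lapply(names(cohort$peakSets), function(id)
  callM3Es(callActiveEnhancers(cohort$peakSets[[id]]$H3K27ac, gm),
           cohort$peakSets[[id]]$H3K4me3, gm))
names(enhSets) <- names(cohort$peakSets)
enhSets[["P01_tumor"]]
#> EnhancerSet: 300 enhancers (60 m3E) for sample 'P01_tumor'

m3e <- lapply(enhSets, function(es) {
  e <- enhancers(es); e[e$class == "m3E"]
})
acFrags <- lapply(cohort$fragmentSets, `[[`, "H3K27ac")
vm3es <- callVm3Es(m3e, acFrags, cohort$pairs)
table(S4Vectors::mcols(vm3es)$direction)
#> gain lost
#>   30   11

unlist(scoreRecovery(vm3es, cohort$truth)[c("sensitivity", "precision")])
#> sensitivity   precision
#>   0.9750000   0.9512195
```

All 30 planted gain loci and 9/10 lost loci are recalled; the extra
calls are two noise-driven loci (precision 0.95). Each called locus
carries its direction, recurrence, binomial p, BH q, cohort fold change
and contributing patients. `runFull()` executes the same chain from a
manifest + GTF on disk and writes BED/TSV results stamped with a
configuration hash (`inst/scripts/m3escan.R` is a command-line wrapper
with `simulate` and `run-all` subcommands).

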