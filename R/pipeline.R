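#' Pipeline configuration with the published default thresholds
#'
#' Defaults encode the analysis constants used throughout: 2 kb TSS
#' exclusion, per-pair fold change 2 (for both VELs and stage-1 Vm3E
#' candidates), cohort mean fold change 1.5 for Vm3Es, significant
#' -percentage cutoff 0.90 with q < 0.05 for VEL recurrence-threshold
#' selection, fixed recurrence 5 for VSELs, 12.5 kb super-enhancer
#' stitching, fold-change pseudocount 0.5, and a QC minimum of 5000
#' peaks per mark.
#'
#' @param ... overrides for any default (unknown names are an error).
#' @return A named list of class \code{"PipelineConfig"}.
#' @examples
#' pipelineConfig(minPeaks = 1000)
#' @export
pipelineConfig <- function(...) {
  cfg <- list(tssExclusionBp = 2000, pairFc = 2.0, cohortFc = 1.5,
              velFc = 2.0, significantFractionCutoff = 0.90,
              qCutoff = 0.05, vselRecurrence = 5L, stitchBp = 12500,
              pseudocount = 0.5, minPeaks = 5000, gap = 0L,
              maxTargetDistanceBp = 5e5, kNearest = 1L, minOverlap = 1L,
              inclusive = TRUE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "PipelineConfig")
}

#' @export
print.PipelineConfig <- function(x, ...) {
  cat("PipelineConfig:\n")
  for (nm in names(x)) cat(sprintf("  %-26s %s\n", nm,
                                   format(x[[nm]])))
  invisible(x)
}

.configHash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(config), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

.stampHash <- function(path, hash) {
  writeLines(c(sprintf("# config_hash=%s", hash), readLines(path)), path)
}

## assemble per-sample peak and fragment sets, from disk or in-memory
.loadSamples <- function(manifest, cohort) {
  ids <- unique(paste0(manifest$patient_id, "_", manifest$tissue))
  peaksBy <- list(); fragsBy <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- paste0(manifest$patient_id[i], "_", manifest$tissue[i])
    mk <- manifest$mark[i]
    if (!is.null(cohort)) {
      peaksBy[[id]][[mk]] <- cohort$peakSets[[id]][[mk]]
      fragsBy[[id]][[mk]] <- cohort$fragmentSets[[id]][[mk]]
    } else {
      peaksBy[[id]][[mk]] <- readPeaks(manifest$peak_path[i],
                                       sampleId = id, mark = mk)
      fragsBy[[id]][[mk]] <- FragmentSet(id, mk,
        peaks(readPeaks(manifest$fragment_path[i], sampleId = id,
                        mark = mk)),
        manifest$total_mapped[i])
    }
  }
  list(ids = ids, peaks = peaksBy, fragments = fragsBy)
}

#' Run the full discovery pipeline
#'
#' Executes, in order: sample QC, TSS-distal enhancer calling, m3E
#' classification, super-enhancer stitching, RPKM quantification,
#' VEL / Vm3E / VSEL calling, and the downstream summaries (fractions,
#' genomic distribution, PCA, target genes). All results are written to
#' \code{outDir} as BED/TSV files stamped with a hash of the
#' configuration; a rerun with identical inputs and configuration is
#' bit-identical.
#'
#' @param manifestPath path to a sample manifest (see [readManifest()]);
#'   ignored when \code{cohort} is given.
#' @param gtfPath path to the gene annotation GTF; ignored when
#'   \code{cohort} is given.
#' @param outDir output directory (created if needed).
#' @param config a [pipelineConfig()].
#' @param cohort optional in-memory bundle from [generateCohort()], used
#'   instead of reading files.
#' @return Invisibly, a list with the per-stage results (\code{qc},
#'   \code{enhancerSets}, \code{superEnhancers}, \code{vels},
#'   \code{vm3es}, \code{vsels}, \code{fractions}, \code{distribution},
#'   \code{pca}, \code{targets}, \code{files}).
#' @export
runFull <- function(manifestPath = NULL, gtfPath = NULL, outDir,
                    config = pipelineConfig(), cohort = NULL) {
  stage <- function(name, expr) {
    t0 <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    r
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(config)

  model <- stage("annotation", {
    if (!is.null(cohort)) cohort$geneModel else readGeneModel(gtfPath)
  })
  manifest <- if (!is.null(cohort)) cohort$manifest else
    readManifest(manifestPath)

  qc <- stage("qc", {
    if (!is.null(cohort)) {
      counts <- vapply(seq_len(nrow(manifest)), function(i)
        length(cohort$peakSets[[paste0(manifest$patient_id[i], "_",
                                       manifest$tissue[i])]][[
          manifest$mark[i]]]), integer(1))
      data.frame(manifest[, c("patient_id", "tissue", "mark")],
                 n_peaks = counts,
                 included = counts >= config$minPeaks &
                   !manifest$patient_id %in%
                     manifest$patient_id[counts < config$minPeaks],
                 reason = ifelse(counts < config$minPeaks,
                                 "low peak count", ""))
    } else qcFilterSamples(manifest, config$minPeaks)
  })
  keepPatients <- unique(qc$patient_id[qc$included])
  if (!length(keepPatients)) stop("stage 'qc' failed: no samples pass QC")
  mf <- manifest[manifest$patient_id %in% keepPatients, ]
  smp <- stage("load", .loadSamples(mf, cohort))
  acFrags <- lapply(smp$fragments, `[[`, "H3K27ac")

  enhSets <- stage("enhancers", {
    out <- list()
    for (id in smp$ids) {
      enh <- callActiveEnhancers(smp$peaks[[id]][["H3K27ac"]], model,
                                 config$tssExclusionBp)
      out[[id]] <- callM3Es(enh, smp$peaks[[id]][["H3K4me3"]], model,
                            config$tssExclusionBp, config$minOverlap)
    }
    out
  })
  superEnh <- stage("super_enhancers", {
    lapply(enhSets, function(es) {
      sig <- rpkm(enhancers(es), acFrags[[sampleId(es)]])
      suppressWarnings(stitchSuperEnhancers(es, sig, config$stitchBp))
    })
  })

  pairs <- data.frame(patient_id = keepPatients,
                      native = paste0(keepPatients, "_native"),
                      tumor = paste0(keepPatients, "_tumor"),
                      stringsAsFactors = FALSE)
  enhGR <- lapply(enhSets, enhancers)
  m3eGR <- lapply(enhSets, function(es) {
    e <- enhancers(es)
    e[S4Vectors::mcols(e)$class == "m3E"]
  })

  vels <- stage("vels", suppressWarnings(callVELs(
    buildPairSignals(enhGR, acFrags, pairs, config$gap),
    fcThreshold = config$velFc,
    significantFractionCutoff = config$significantFractionCutoff,
    qCutoff = config$qCutoff, pseudocount = config$pseudocount,
    gap = config$gap, inclusive = config$inclusive)))
  vm3es <- stage("vm3es", suppressWarnings(callVm3Es(
    m3eGR, acFrags, pairs, pairFc = config$pairFc,
    cohortFc = config$cohortFc, pseudocount = config$pseudocount,
    gap = config$gap, minOverlap = config$minOverlap)))
  vsels <- stage("vsels", suppressWarnings(callVSELs(
    buildPairSignals(superEnh, acFrags, pairs, config$gap),
    recurrenceThreshold = config$vselRecurrence,
    fcThreshold = config$velFc, pseudocount = config$pseudocount,
    gap = config$gap, inclusive = config$inclusive)))

  summaries <- stage("summaries", {
    fr <- fractionReport(enhSets,
                         lapply(smp$peaks, `[[`, "H3K4me3"),
                         config$minOverlap)
    m3eMerged <- if (length(m3eGR))
      GenomicRanges::granges(mergeIntervals(
        suppressWarnings(do.call(c, unname(m3eGR))), config$gap)) else
      GenomicRanges::GRanges()
    dist <- annotateGenomicDistribution(m3eMerged, model,
                                        config$tssExclusionBp)
    pca <- NULL
    if (length(vm3es) >= 2L) {
      se <- buildSignalMatrix(GenomicRanges::granges(vm3es),
                              unname(acFrags),
                              tissues = sub("^.*_", "",
                                            names(acFrags)))
      pca <- pcaClassification(se)
    }
    tg <- assignTargetGenes(vm3es, model, config$maxTargetDistanceBp,
                            config$kNearest)
    list(fractions = fr, m3eMerged = m3eMerged, distribution = dist,
         pca = pca, targets = tg)
  })

  files <- stage("write", {
    wrote <- character(0)
    wtsv <- function(df, name) {
      p <- file.path(outDir, name)
      utils::write.table(df, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      .stampHash(p, hash)
      wrote <<- c(wrote, p)
    }
    wtsv(qc, "qc_report.tsv")
    wtsv(summaries$fractions, "fractions.tsv")
    wtsv(data.frame(category = names(summaries$distribution),
                    count = as.integer(summaries$distribution)),
         "genomic_distribution.tsv")
    if (!is.null(summaries$pca)) wtsv(summaries$pca,
                                      "pca_coordinates.tsv")
    wtsv(data.frame(
      locus = if (length(vm3es)) sprintf("%s:%d-%d",
        as.character(GenomicRanges::seqnames(vm3es)),
        GenomicRanges::start(vm3es) - 1L, GenomicRanges::end(vm3es))
        else character(0),
      target_genes = vapply(as.list(summaries$targets), paste,
                            character(1), collapse = ",")),
      "target_genes.tsv")
    for (cls in list(list("vel", vels), list("vm3e", vm3es),
                     list("vsel", vsels))) {
      for (d in VARIANT_DIRECTIONS) {
        sub <- cls[[2]][S4Vectors::mcols(cls[[2]])$direction == d]
        base <- sprintf("%s_%s", cls[[1]], d)
        for (fmt in c("bed", "tsv")) {
          p <- file.path(outDir, paste0(base, ".", fmt))
          writeLoci(sub, p, format = fmt)
          .stampHash(p, hash)
          wrote <- c(wrote, p)
        }
      }
    }
    p <- file.path(outDir, "run_info.tsv")
    utils::write.table(
      data.frame(key = c("config_hash", "n_patients", "n_vels",
                         "n_vm3es", "n_vsels"),
                 value = c(hash, length(keepPatients), length(vels),
                           length(vm3es), length(vsels))),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    c(wrote, p)
  })

  invisible(list(qc = qc, enhancerSets = enhSets,
                 superEnhancers = superEnh, vels = vels, vm3es = vm3es,
                 vsels = vsels, fractions = summaries$fractions,
                 distribution = summaries$distribution,
                 pca = summaries$pca, targets = summaries$targets,
                 configHash = hash, files = files))
}

#' Simulate a runnable input bundle
#'
#' Thin wrapper over [generateCohort()] that always writes the bundle
#' (GTF, peak/fragment BED files, manifest, truth table) to disk.
#'
#' @param config a [SimConfig-class].
#' @param dir output directory.
#' @return The bundle list, with \code{manifest} carrying file paths.
#' @export
simulateBundle <- function(config, dir) {
  generateCohort(config, dir = dir)
}
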