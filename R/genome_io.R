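#' Read a BED-family peak file into a PeakSet
#'
#' Parses BED3+, narrowPeak or broadPeak. Track, browser and comment lines
#' are skipped. Input coordinates are 0-based half-open and are converted
#' to the 1-based closed convention of \code{GRanges}. The \code{name}
#' column (4) and the format's signal column (5 for BED, 7 for
#' narrowPeak/broadPeak, the MACS-style signalValue) are preserved as
#' \code{name} and \code{score} metadata columns.
#'
#' @param path path to the peak file.
#' @param format \code{"auto"} infers narrowPeak/broadPeak from the file
#'   extension and falls back to BED.
#' @param sampleId,mark stored in the returned [PeakSet-class].
#' @param chromStyle \code{"asis"} keeps chromosome names verbatim;
#'   \code{"chr"}/\code{"nochr"} harmonize the \code{chr} prefix for
#'   mixed-source inputs.
#' @return A [PeakSet-class] with sorted intervals; empty files give an
#'   empty set.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200", "chr1\t50\t80"), f)
#' peaks(readPeaks(f, sampleId = "s1"))
#' @export
readPeaks <- function(path, format = c("auto", "bed", "narrowPeak",
                                       "broadPeak"),
                      sampleId = basename(path),
                      mark = c("H3K27ac", "H3K4me3", "TF"),
                      chromStyle = c("asis", "chr", "nochr")) {
  format <- match.arg(format)
  mark <- match.arg(mark)
  chromStyle <- match.arg(chromStyle)
  if (!file.exists(path)) stop("peak file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("narrowpeak", "broadpeak"))
      c(narrowpeak = "narrowPeak", broadpeak = "broadPeak")[[ext]] else "bed"
  }
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(PeakSet(sampleId, mark, GenomicRanges::GRanges()))

  fields <- strsplit(lines, "[ \t]+")
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop(sprintf("line %d: fewer than 3 columns", lineNo[which(ncol < 3L)[1]]))
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad))
    stop(sprintf("line %d: non-integer coordinates", lineNo[which(bad)[1]]))
  bad <- start >= end | start < 0L
  if (any(bad))
    stop(sprintf("line %d: invalid interval (start >= end or negative)",
                 lineNo[which(bad)[1]]))

  chrom <- .restyleChrom(chrom, chromStyle)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  nm <- ifelse(ncol >= 4L, vapply(fields, function(f)
    if (length(f) >= 4L) f[[4L]] else NA_character_, character(1)),
    NA_character_)
  scoreCol <- if (format %in% c("narrowPeak", "broadPeak")) 7L else 5L
  sc <- suppressWarnings(as.numeric(vapply(fields, function(f)
    if (length(f) >= scoreCol) f[[scoreCol]] else NA_character_,
    character(1))))
  if (any(!is.na(nm))) S4Vectors::mcols(gr)$name <- nm
  if (any(!is.na(sc))) S4Vectors::mcols(gr)$score <- sc
  PeakSet(sampleId, mark, gr)
}

.restyleChrom <- function(chrom, style) {
  switch(style,
    asis = chrom,
    chr = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom)),
    nochr = sub("^chr", "", chrom))
}

#' Read a GTF gene annotation into a GeneModel
#'
#' GTF coordinates are 1-based inclusive and are kept in the 1-based
#' \code{GRanges} convention. One representative transcript is chosen per
#' gene - the longest span - and its 5' end (strand-aware) becomes the
#' gene's TSS. Genes without exon records are skipped with a warning.
#'
#' @param path path to a GTF file.
#' @param feature \code{"transcript"} anchors TSS selection on transcript
#'   spans (default); \code{"gene"} uses the gene span directly when
#'   annotated.
#' @param chromStyle see [readPeaks()].
#' @return A [GeneModel-class].
#' @export
readGeneModel <- function(path, feature = c("transcript", "gene"),
                          chromStyle = c("asis", "chr", "nochr")) {
  feature <- match.arg(feature)
  chromStyle <- match.arg(chromStyle)
  gtf <- rtracklayer::import(path, format = "gtf")
  GenomeInfoDb::seqlevels(gtf) <-
    .restyleChrom(GenomeInfoDb::seqlevels(gtf), chromStyle)
  ex <- gtf[gtf$type == "exon"]
  geneIds <- unique(gtf$gene_id[!is.na(gtf$gene_id)])
  if (!length(ex) || !length(geneIds))
    stop("no exon records found in ", path)

  keyGene <- character(0); spans <- list(); exons <- list()
  exByTx <- S4Vectors::split(ex, paste(ex$gene_id, ex$transcript_id))
  txGene <- vapply(strsplit(names(exByTx), " "), `[[`, character(1), 1L)
  txSpan <- unlist(range(exByTx))
  dropped <- character(0)
  for (g in geneIds) {
    idx <- which(txGene == g)
    if (!length(idx)) { dropped <- c(dropped, g); next }
    best <- idx[which.max(GenomicRanges::width(txSpan[idx]))]
    if (feature == "gene") {
      grow <- gtf[gtf$type == "gene" & gtf$gene_id == g]
      span <- if (length(grow)) GenomicRanges::granges(grow[1]) else
        GenomicRanges::granges(txSpan[best])
    } else span <- GenomicRanges::granges(txSpan[best])
    keyGene <- c(keyGene, g)
    spans <- c(spans, list(span))
    exons <- c(exons, list(.sortGR(GenomicRanges::granges(exByTx[[best]]))))
  }
  if (length(dropped))
    warning("skipped ", length(dropped), " gene(s) with no exons: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  genes <- unlist(methods::as(spans, "GRangesList"))
  names(genes) <- keyGene
  exl <- methods::as(exons, "GRangesList")
  names(exl) <- keyGene
  GeneModel(genes, exl)
}

#' Write loci to BED or TSV
#'
#' BED output is 0-based half-open and round-trips exactly through
#' [readPeaks()]. TSV output carries the variant-locus schema: columns
#' \code{locus}, \code{direction}, \code{recurrence}, \code{p}, \code{q},
#' \code{fold_change}, \code{class} (missing annotations become \code{NA};
#' zero loci give a header-only file).
#'
#' @param loci \code{GRanges}, optionally with the variant-locus metadata
#'   columns \code{direction}, \code{recurrence}, \code{p_value},
#'   \code{q_value}, \code{cohort_fc}, \code{class}.
#' @param path output file path.
#' @param format \code{"bed"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
writeLoci <- function(loci, path, format = c("bed", "tsv")) {
  format <- match.arg(format)
  if (is.null(loci)) stop("'loci' must not be NULL")
  mc <- S4Vectors::mcols(loci)
  get <- function(col, default) if (!is.null(mc[[col]])) mc[[col]] else
    rep(default, length(loci))
  if (format == "bed") {
    name <- get("name", NA_character_)
    cls <- get("class", NA_character_)
    dir <- get("direction", NA_character_)
    auto <- ifelse(is.na(cls), NA_character_,
                   ifelse(is.na(dir), cls, paste(cls, dir, sep = "_")))
    name <- ifelse(is.na(name), auto, name)
    name[is.na(name)] <- "."
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(loci)),
                     start = GenomicRanges::start(loci) - 1L,
                     end = GenomicRanges::end(loci),
                     name = name,
                     score = get("recurrence", 0))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(
      locus = sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(loci)),
                      GenomicRanges::start(loci) - 1L,
                      GenomicRanges::end(loci)),
      direction = get("direction", NA_character_),
      recurrence = get("recurrence", NA_integer_),
      p = get("p_value", NA_real_),
      q = get("q_value", NA_real_),
      fold_change = get("cohort_fc", NA_real_),
      class = get("class", NA_character_))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Write a GeneModel as GTF
#'
#' Emits transcript and exon records (1-based inclusive) that
#' [readGeneModel()] reads back into an identical model.
#'
#' @param model a [GeneModel-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGtf <- function(model, path) {
  genes <- geneSpans(model)
  exl <- geneExons(model)
  rows <- character(0)
  for (i in seq_along(genes)) {
    g <- names(genes)[i]
    attr <- sprintf('gene_id "%s"; transcript_id "%s.t1";', g, g)
    chrom <- as.character(GenomicRanges::seqnames(genes))[i]
    strand <- as.character(GenomicRanges::strand(genes))[i]
    rows <- c(rows,
      sprintf("%s\tm3Escan\ttranscript\t%d\t%d\t.\t%s\t.\t%s", chrom,
              GenomicRanges::start(genes)[i], GenomicRanges::end(genes)[i],
              strand, attr),
      sprintf("%s\tm3Escan\texon\t%d\t%d\t.\t%s\t.\t%s", chrom,
              GenomicRanges::start(exl[[i]]), GenomicRanges::end(exl[[i]]),
              strand, attr))
  }
  writeLines(rows, path)
  invisible(path)
}

#' Read a sample manifest
#'
#' Tab-separated with header columns \code{patient_id}, \code{tissue}
#' (\code{native}/\code{tumor}), \code{mark}, \code{peak_path},
#' \code{fragment_path}, \code{total_mapped}. Relative paths are resolved
#' against the manifest's directory. Every patient must contribute both
#' tissues for H3K27ac.
#'
#' @param path manifest path.
#' @param checkPaths verify that all referenced files exist (default TRUE).
#' @return A \code{data.frame} with resolved paths.
#' @export
readManifest <- function(path, checkPaths = TRUE) {
  mf <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("patient_id", "tissue", "mark", "peak_path", "fragment_path",
            "total_mapped")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  if (!all(mf$tissue %in% TISSUES))
    stop("manifest 'tissue' must be one of: ", paste(TISSUES, collapse = ", "))
  if (!all(mf$mark %in% CHIP_MARKS))
    stop("manifest 'mark' must be one of: ",
         paste(CHIP_MARKS, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(is.na(p) | p == "" | grepl("^/", p), p,
                                file.path(base, p))
  mf$peak_path <- resolve(mf$peak_path)
  mf$fragment_path <- resolve(mf$fragment_path)
  ac <- mf[mf$mark == "H3K27ac", ]
  byPatient <- split(ac$tissue, ac$patient_id)
  incomplete <- names(byPatient)[!vapply(byPatient, function(t)
    all(TISSUES %in% t), logical(1))]
  if (length(incomplete))
    stop("patient(s) missing a tissue for H3K27ac: ",
         paste(incomplete, collapse = ", "))
  if (checkPaths) {
    paths <- stats::na.omit(c(mf$peak_path, mf$fragment_path))
    absent <- paths[!file.exists(paths)]
    if (length(absent))
      stop("manifest references missing file(s): ",
           paste(utils::head(absent, 3), collapse = ", "))
  }
  mf
}
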