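# Readers/writers for the plain-text interchange formats: counts TSV,
# BED-like annotation TSV (1-based inclusive), sample metadata TSV, GMT
# gene sets and ground-truth JSON.

#' Write / read a counts matrix with sample metadata
#'
#' The counts TSV has a \code{gene_id} column followed by one column per
#' sample; the metadata TSV has columns \code{sample}, \code{condition},
#' \code{timepoint}, \code{group}.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with a
#'   \code{counts} assay.
#' @param countsPath,metaPath file paths.
#' @return \code{writeCounts} returns the paths invisibly;
#'   \code{readCounts} returns a \code{SummarizedExperiment}.
#' @export
writeCounts <- function(se, countsPath, metaPath) {
  m <- SummarizedExperiment::assay(se, "counts")
  writeTSV(data.frame(gene_id = rownames(m), m, check.names = FALSE), countsPath)
  writeTSV(
    as.data.frame(SummarizedExperiment::colData(se)), metaPath
  )
  invisible(c(countsPath, metaPath))
}

#' @rdname writeCounts
#' @export
readCounts <- function(countsPath, metaPath) {
  df <- readTSV(countsPath)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  meta <- readTSV(metaPath)
  if (!all(colnames(m) %in% meta$sample)) {
    stop("metadata does not cover every sample column")
  }
  meta <- meta[match(colnames(m), meta$sample), , drop = FALSE]
  rownames(meta) <- meta$sample
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(meta)
  )
}

#' Write / read a BED-like gene annotation
#'
#' Columns: chrom, start, end, gene_id, biotype, strand,
#' transcript_length. Coordinates are 1-based and inclusive.
#'
#' @param annotation a [GenomicRanges::GRanges] as from
#'   [generateAnnotation()].
#' @param path file path.
#' @return \code{readAnnotation} returns a \code{GRanges} named by gene id.
#' @export
writeAnnotation <- function(annotation, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(annotation)),
    start = GenomicRanges::start(annotation),
    end = GenomicRanges::end(annotation),
    gene_id = annotation$gene_id,
    biotype = annotation$biotype,
    strand = as.character(GenomicRanges::strand(annotation)),
    transcript_length = annotation$transcript_length
  )
  writeTSV(df, path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
  df <- readTSV(path)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand,
    gene_id = df$gene_id, biotype = df$biotype,
    transcript_length = df$transcript_length
  )
  names(gr) <- df$gene_id
  gr
}

#' Write / read GMT gene-set files
#'
#' Standard tab-separated GMT: term id, description, then member genes.
#'
#' @param terms a [TermMap-class].
#' @param path file path.
#' @return \code{readGMT} returns a \code{TermMap}.
#' @export
writeGMT <- function(terms, path) {
  lines <- vapply(seq_along(terms@ids), function(i) {
    paste(c(terms@ids[i], terms@termNames[i], terms@genes[[i]]),
      collapse = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(parts) >= 3L
  parts <- parts[keep]
  termMap(
    ids = vapply(parts, `[[`, character(1), 1L),
    termNames = vapply(parts, `[[`, character(1), 2L),
    genes = lapply(parts, function(p) p[-(1:2)])
  )
}

#' Serialize a ground-truth record to JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(
    list(
      modulated_genes = modulatedGenes(truth),
      cis_pairs = plantedCisPairs(truth),
      signature_genes = signatureGenes(truth),
      nrir_like_id = nrirLikeId(truth),
      planted_module = plantedModule(truth)
    ),
    path,
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
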