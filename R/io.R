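# Plain-text readers/writers for the pipeline's interchange formats.
# All files are UTF-8, tab-separated, with '#' comment lines permitted.

.readTsv <- function(path, ...) {
  read.delim(path, sep = "\t", comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

.writeTsv <- function(x, path, rowNames = FALSE) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = rowNames,
              col.names = TRUE)
  invisible(path)
}

#' Read a counts table and sample metadata
#'
#' @param countsPath TSV, genes in rows (first column = gene id), samples
#'   in columns.
#' @param metaPath TSV with columns sample_id, ecotype, condition, time,
#'   replicate.
#' @return a SummarizedExperiment via \code{\link{stressCountSet}}.
#' @export
readCounts <- function(countsPath, metaPath) {
  tab <- .readTsv(countsPath)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  meta <- .readTsv(metaPath)
  stressCountSet(counts, meta)
}

#' Write a counts SummarizedExperiment to TSV
#'
#' @param se SummarizedExperiment with assay "counts".
#' @param countsPath,metaPath output files.
#' @return invisibly, the counts path.
#' @export
writeCounts <- function(se, countsPath, metaPath) {
  y <- .counts(se)
  tab <- data.frame(gene = rownames(y), y, check.names = FALSE)
  .writeTsv(tab, countsPath)
  .writeTsv(as.data.frame(SummarizedExperiment::colData(se)), metaPath)
  invisible(countsPath)
}

#' Read a TF list (one gene id per line)
#'
#' @param path text file; blank and '#' lines are skipped.
#' @return character vector.
#' @export
readTfList <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read an ortholog map TSV (query_gene, ref_species, ref_gene, group_id)
#' @param path TSV file.
#' @return data.frame.
#' @export
readOrthologMap <- function(path) .readTsv(path)

#' Read reference TF-TG interaction sets (source, ref_species, tf, target)
#' @param path TSV file.
#' @return data.frame.
#' @export
readReferenceSets <- function(path) .readTsv(path)

#' Read gene-to-GO annotations (gene, go_id, aspect)
#' @param path TSV file.
#' @return data.frame.
#' @export
readAnnotations <- function(path) .readTsv(path)

#' Write a Grn edge list to TSV (tf, tg, stage, pcc, cs, sign)
#'
#' @param net a \linkS4class{Grn}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGrn <- function(net, path) {
  e <- edgeTable(net)
  e$stage <- networkStage(net)
  .writeTsv(e[, c("tf", "tg", "stage", "pcc", "cs", "sign")], path)
}

#' Read a Grn edge list written by \code{\link{writeGrn}}
#'
#' @param path TSV file.
#' @return a \linkS4class{Grn}; the stage is taken from the file, the
#'   pccCut recorded as the smallest |pcc| present.
#' @export
readGrn <- function(path) {
  e <- .readTsv(path)
  stage <- if (nrow(e)) e$stage[1] else "initial"
  cut <- if (nrow(e)) min(abs(e$pcc)) else 0
  .newGrn(e[, c("tf", "tg", "pcc", "cs", "sign")], stage, cut)
}

#' Write all simulated inputs of a study to a directory
#'
#' Produces counts.tsv, metadata.tsv, tf_list.txt, ortholog_map.tsv,
#' reference_interactions.tsv, go_annotations.tsv, go.obo and
#' truth_edges.tsv. Byte-identical for identical inputs.
#'
#' @param sim result of \code{\link{simulateStudy}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCounts(sim$se, file.path(dir, "counts.tsv"),
              file.path(dir, "metadata.tsv"))
  writeLines(tfIds(sim$network), file.path(dir, "tf_list.txt"))
  .writeTsv(sim$orthologMap, file.path(dir, "ortholog_map.tsv"))
  .writeTsv(sim$referenceSets, file.path(dir, "reference_interactions.tsv"))
  .writeTsv(sim$annotations, file.path(dir, "go_annotations.tsv"))
  writeObo(sim$goDag, file.path(dir, "go.obo"))
  .writeTsv(sim$truth@orthologTruth, file.path(dir, "truth_edges.tsv"))
  invisible(dir)
}
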