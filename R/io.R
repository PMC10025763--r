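#' Read and write expression matrices, gene lists and attributions
#'
#' Expression matrices are TSV with gene IDs in the first column and sample
#' IDs in the header; tissue labels travel in a two-column sidecar TSV
#' (sample_id, tissue). Ground truth is JSON. Attribution vectors are
#' two-column TSV (gene_id, score). All writers and readers round-trip.
#'
#' @param cohort a [TranscriptomeCohort-class].
#' @param file path of the matrix TSV.
#' @param labelsFile path of the sample-to-tissue sidecar TSV.
#' @name cohort-io
NULL

#' @rdname cohort-io
#' @export
writeCohortTSV <- function(cohort, file, labelsFile = NULL) {
  if (is.null(labelsFile)) labelsFile <- paste0(file, ".labels")
  v <- exprValues(cohort)
  df <- data.frame(gene_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = colnames(v),
                         tissue = tissueLabels(cohort)),
              labelsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(file, labelsFile))
}

#' @rdname cohort-io
#' @export
readCohortTSV <- function(file, labelsFile = NULL) {
  if (is.null(labelsFile)) labelsFile <- paste0(file, ".labels")
  df <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "gene_id")
    .stopf("%s: first column must be 'gene_id'", file)
  v <- as.matrix(df[, -1L, drop = FALSE])
  rownames(v) <- df$gene_id
  if (!is.numeric(v) || anyNA(v))
    .stopf("%s: non-numeric or missing expression values", file)
  lab <- read.delim(labelsFile, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "tissue") %in% colnames(lab)))
    .stopf("%s: needs columns sample_id and tissue", labelsFile)
  miss <- setdiff(colnames(v), lab$sample_id)
  if (length(miss))
    .stopf("%s: no tissue label for sample '%s'", labelsFile, miss[1L])
  tissue <- lab$tissue[match(colnames(v), lab$sample_id)]
  TranscriptomeCohort(v, tissue)
}

#' @rdname cohort-io
#' @param truth a ground-truth list (see [generateCohort()]).
#' @export
writeGroundTruthJSON <- function(truth, file) {
  truth$design <- unclass(truth$design)
  jsonlite::write_json(truth, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname cohort-io
#' @export
readGroundTruthJSON <- function(file) {
  truth <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (!is.null(truth$design)) class(truth$design) <- "SyntheticDesign"
  truth
}

#' Read a one-symbol-per-line gene annotation list
#'
#' Blank lines and `#` comments are skipped; duplicates are removed with a
#' warning.
#'
#' @param file path to the list.
#' @return Character vector of gene symbols.
#' @export
readGeneList <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (anyDuplicated(lines)) {
    warning(sprintf("%s: %d duplicated symbols removed", file,
                    sum(duplicated(lines))), call. = FALSE)
    lines <- unique(lines)
  }
  lines
}

#' @rdname cohort-io
#' @param attribution an [Attribution-class] or named score vector.
#' @export
writeAttributionTSV <- function(attribution, file) {
  s <- if (is(attribution, "Attribution")) scores(attribution)
       else attribution
  write.table(data.frame(gene_id = names(s), score = s),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname cohort-io
#' @export
readAttributionTSV <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "score") %in% colnames(df)))
    .stopf("%s: needs columns gene_id and score", file)
  if (!is.numeric(df$score) || any(!is.finite(df$score)))
    .stopf("%s: attribution scores must be finite numbers", file)
  stats::setNames(df$score, df$gene_id)
}
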