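#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats rnorm rlnorm runif median cor sd qnorm pnorm
#'   p.adjust wilcox.test hclust as.dist quantile
#' @importFrom utils combn read.delim write.table head
NULL

#' Expression cohort with tissue labels and optional ground truth
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' genes-by-samples matrix of log2(TPM+1) values in the `"log2tpm"` assay,
#' per-sample tissue labels in `colData(x)$tissue`, and (for synthetic
#' cohorts) the planted ground truth in `metadata(x)$groundTruth`.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("TranscriptomeCohort", contains = "SummarizedExperiment")

setValidity("TranscriptomeCohort", function(object) {
  msgs <- character()
  if (!"log2tpm" %in% assayNames(object))
    msgs <- c(msgs, "assay 'log2tpm' is required")
  else {
    v <- assay(object, "log2tpm")
    if (!all(is.finite(v))) msgs <- c(msgs, "expression values must be finite")
    else if (any(v < 0)) msgs <- c(msgs, "log2(TPM+1) values must be >= 0")
  }
  if (!"tissue" %in% colnames(colData(object)))
    msgs <- c(msgs, "colData column 'tissue' is required")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TranscriptomeCohort
#'
#' @param values numeric matrix of log2(TPM+1), genes in rows, samples in
#'   columns.
#' @param tissue character vector of per-sample tissue/class labels.
#' @param geneIds,sampleIds identifiers; default to dimnames of `values`.
#' @param groundTruth optional list describing planted structure (see
#'   [generateCohort()]).
#' @return A [TranscriptomeCohort-class] object.
#' @export
TranscriptomeCohort <- function(values, tissue, geneIds = rownames(values),
                                sampleIds = colnames(values),
                                groundTruth = NULL) {
  values <- as.matrix(values)
  if (is.null(geneIds)) geneIds <- sprintf("g%05d", seq_len(nrow(values)))
  if (is.null(sampleIds)) sampleIds <- sprintf("s%05d", seq_len(ncol(values)))
  if (length(geneIds) != nrow(values) || length(sampleIds) != ncol(values))
    .stopf("gene/sample id lengths must match matrix dimensions")
  if (length(tissue) != ncol(values))
    .stopf("'tissue' must have one label per sample")
  dimnames(values) <- list(geneIds, sampleIds)
  se <- SummarizedExperiment(
    assays = list(log2tpm = values),
    colData = DataFrame(tissue = as.character(tissue), row.names = sampleIds))
  obj <- new("TranscriptomeCohort", se)
  if (!is.null(groundTruth)) metadata(obj)$groundTruth <- groundTruth
  obj
}

#' @describeIn TranscriptomeCohort per-sample tissue labels.
#' @param x a `TranscriptomeCohort`.
#' @export
tissueLabels <- function(x) colData(x)$tissue

#' @describeIn TranscriptomeCohort expression matrix (genes x samples).
#' @export
exprValues <- function(x) assay(x, "log2tpm")

#' @describeIn TranscriptomeCohort planted ground truth, or NULL.
#' @export
groundTruth <- function(x) metadata(x)$groundTruth

setMethod("show", "TranscriptomeCohort", function(object) {
  cat("TranscriptomeCohort:", nrow(object), "genes x", ncol(object),
      "samples\n")
  tab <- table(tissueLabels(object))
  cat("tissues:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "),
      "\n")
  if (!is.null(groundTruth(object)))
    cat("ground truth: planted markers / HK / DE gene sets attached\n")
})

#' Neural-network tissue classifier
#'
#' Holds the layer stack, configuration, class levels and training history of
#' an MLP or CNN tissue classifier. Create with [buildModel()] and fit with
#' [trainClassifier()]. All forward/backward arithmetic is double precision.
#'
#' @slot arch "MLP" or "CNN".
#' @slot config the [modelConfig()] list used to build the network.
#' @slot layers internal layer stack (weights, batch-norm statistics, ...).
#' @slot classLevels ordered class labels mapped to output units.
#' @slot geneIds gene identifiers in input order.
#' @slot geneOrder permutation applied to genes before the CNN grid reshape.
#' @slot history per-epoch data.frame of loss, accuracy and learning rate.
#' @slot trained logical flag.
#' @export
setClass("TissueClassifier", representation(
  arch = "character", config = "list", layers = "list",
  classLevels = "character", geneIds = "character", geneOrder = "integer",
  history = "data.frame", trained = "logical"))

setMethod("show", "TissueClassifier", function(object) {
  cat(sprintf("TissueClassifier <%s>: %d genes -> %d classes [%s]\n",
              object@arch, object@config$nGenes, object@config$nClasses,
              if (object@trained) "trained" else "untrained"))
  if (nrow(object@history)) {
    last <- object@history[nrow(object@history), ]
    cat(sprintf("  %d epochs, final loss %.4f, training accuracy %.3f\n",
                nrow(object@history), last$loss, last$accuracy))
  }
})

#' @describeIn TissueClassifier ordered class labels of the output layer.
#' @param x a `TissueClassifier`.
#' @export
classLevels <- function(x) x@classLevels

#' Per-gene attribution scores for one (sample, explainer, model) call
#'
#' @slot scores named numeric vector, one contribution score per gene.
#' @slot sampleId,explainerId,modelId,replicateId bookkeeping identifiers.
#' @slot targetClass class whose pre-softmax score was attributed.
#' @slot reference short description of the baseline used (or "none").
#' @export
setClass("Attribution", representation(
  scores = "numeric", sampleId = "character", explainerId = "character",
  modelId = "character", replicateId = "character", targetClass = "character",
  reference = "character"))

#' @describeIn Attribution numeric score vector (named by gene).
#' @param x an `Attribution`.
#' @export
scores <- function(x) x@scores

setMethod("show", "Attribution", function(object) {
  cat(sprintf("Attribution [%s] sample=%s target=%s (%d genes)\n",
              object@explainerId, object@sampleId, object@targetClass,
              length(object@scores)))
  top <- head(sort(object@scores, decreasing = TRUE), 5L)
  cat("  top genes:", paste(sprintf("%s=%.3g", names(top), top),
                            collapse = ", "), "\n")
})

#' Pairwise reproducibility of a replicate set of attributions
#'
#' All unordered replicate pairs scored by Spearman correlation of the gene
#' contribution scores and by the fraction of shared gene IDs among the top-k
#' contributing genes.
#'
#' @slot pairwiseSpearman,pairwiseOverlap numeric vectors of length
#'   `choose(nReplicates, 2)`.
#' @slot k top-k cutoff used for the overlap.
#' @slot nReplicates number of replicates compared.
#' @slot axis which axis of variability the replicates span (e.g.
#'   "intra_model", "inter_model", "aggregated").
#' @slot params free-form protocol parameters.
#' @export
setClass("ReproducibilityReport", representation(
  pairwiseSpearman = "numeric", pairwiseOverlap = "numeric", k = "integer",
  nReplicates = "integer", axis = "character", params = "list"))

#' @describeIn ReproducibilityReport mean pairwise Spearman coefficient
#'   (NA values from degenerate rank variance are dropped).
#' @param x a `ReproducibilityReport`.
#' @export
meanSpearman <- function(x) mean(x@pairwiseSpearman, na.rm = TRUE)

#' @describeIn ReproducibilityReport mean pairwise top-k overlap fraction.
#' @export
meanOverlap <- function(x) mean(x@pairwiseOverlap, na.rm = TRUE)

setMethod("show", "ReproducibilityReport", function(object) {
  cat(sprintf(
    "ReproducibilityReport: %d replicates (%s), %d pairs\n",
    object@nReplicates, object@axis, length(object@pairwiseSpearman)))
  cat(sprintf("  mean Spearman %.3f, mean top-%d overlap %.3f\n",
              meanSpearman(object), object@k, meanOverlap(object)))
})
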