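.asScoreMatrix <- function(attributions) {
  if (is.matrix(attributions)) return(attributions)
  if (is.list(attributions)) {
    vecs <- lapply(attributions, function(a)
      if (is(a, "Attribution")) scores(a) else a)
    return(do.call(rbind, vecs))
  }
  matrix(attributions, nrow = 1L,
         dimnames = list(NULL, names(attributions)))
}

#' Top contributing genes per sample or per tissue
#'
#' Ranks genes by descending contribution score with a deterministic
#' gene-ID tie-break. At `level = "tissue"` the per-sample score vectors
#' are first averaged within each tissue.
#'
#' @param attributions a samples-by-genes score matrix (rownames = sample
#'   ids, colnames = gene ids) or a list of score vectors /
#'   [Attribution-class] objects.
#' @param level `"sample"` or `"tissue"`.
#' @param k list length (default 100).
#' @param tissueLabels per-sample tissue labels (required at tissue level).
#' @return Named list of ranked gene-ID vectors of length `k`.
#' @export
topContributingGenes <- function(attributions, level = c("sample",
                                                         "tissue"),
                                 k = 100L, tissueLabels = NULL) {
  level <- match.arg(level)
  m <- .asScoreMatrix(attributions)
  if (!all(is.finite(m))) .stopf("attribution scores must be finite")
  if (k > ncol(m)) .stopf("k (%d) exceeds the gene universe (%d)", k,
                          ncol(m))
  if (level == "tissue") {
    if (is.null(tissueLabels) || length(tissueLabels) != nrow(m))
      .stopf("'tissueLabels' must label every attribution row")
    m <- do.call(rbind, lapply(split(seq_len(nrow(m)), tissueLabels),
                               function(i) colMeans(m[i, , drop = FALSE])))
  } else if (is.null(rownames(m))) {
    rownames(m) <- sprintf("sample%03d", seq_len(nrow(m)))
  }
  out <- lapply(seq_len(nrow(m)), function(i) topGenes(m[i, ], k))
  names(out) <- rownames(m)
  attr(out, "k") <- as.integer(k)
  out
}

# per-tissue medians on the TPM scale, genes x tissues
.tissueMedianTpm <- function(cohort) {
  v <- 2^exprValues(cohort) - 1
  labels <- tissueLabels(cohort)
  do.call(cbind, lapply(split(seq_along(labels), labels), function(i)
    apply(v[, i, drop = FALSE], 1L, median)))
}

#' Housekeeping genes
#'
#' A gene is housekeeping if, on the back-transformed TPM scale, its
#' per-tissue median expression is at least 1 TPM in every tissue and the
#' ratio of the largest to the smallest per-tissue median is below 2.
#'
#' @param cohort a [TranscriptomeCohort-class] with >= 2 tissues.
#' @return Character vector of gene IDs.
#' @export
housekeepingGenes <- function(cohort) {
  med <- .tissueMedianTpm(cohort)
  if (ncol(med) < 2L) .stopf("need >= 2 tissues")
  lo <- apply(med, 1L, min)
  hi <- apply(med, 1L, max)
  rownames(med)[lo >= 1 & hi / lo < 2]
}

#' Tissue-enhanced genes (surrogate rule)
#'
#' A gene is tissue-enhanced for tissue `t` if its median TPM in `t` is at
#' least `minTpm` and at least `foldThreshold` times the mean of the other
#' tissues' medians. This is a self-contained surrogate for
#' tissue-enhanced classification from expression medians.
#'
#' @param cohort a [TranscriptomeCohort-class] with >= 2 tissues.
#' @param foldThreshold fold over the mean of other tissues' medians
#'   (default 5).
#' @param minTpm minimum median TPM in the enhanced tissue (default 1).
#' @return Named list: tissue -> character vector of gene IDs.
#' @export
tissueSpecificGenes <- function(cohort, foldThreshold = 5, minTpm = 1) {
  med <- .tissueMedianTpm(cohort)
  if (ncol(med) < 2L) .stopf("need >= 2 tissues")
  out <- lapply(seq_len(ncol(med)), function(j) {
    others <- rowMeans(med[, -j, drop = FALSE])
    hit <- med[, j] >= minTpm & med[, j] >= foldThreshold * others
    rownames(med)[hit]
  })
  names(out) <- colnames(med)
  out
}

#' Mann-Whitney differential expression between two groups
#'
#' Per gene: a two-sided Mann-Whitney U test (normal approximation with
#' tie correction via [stats::wilcox.test()]), Benjamini-Hochberg FDR
#' across genes, and a fold change computed from median TPM with a
#' pseudocount: `fold = max(mCancer, mNormal) / min(mCancer, mNormal)`
#' after adding `pseudocount` TPM to both medians. A gene passes if
#' `fdr <= fdrThreshold` and `fold >= fcThreshold`.
#'
#' @param normal,cancer [TranscriptomeCohort-class] objects or
#'   genes-by-samples matrices of log2(TPM+1) over the same genes; each
#'   group needs >= 3 samples.
#' @param fdrThreshold FDR cutoff (default 0.001).
#' @param fcThreshold fold-change cutoff (default 3).
#' @param pseudocount TPM pseudocount for the fold ratio (default 0.01).
#' @return data.frame(gene, U, p, fdr, fold, direction, pass); `direction`
#'   is "up"/"down" in cancer relative to normal.
#' @export
differentialExpression <- function(normal, cancer, fdrThreshold = 0.001,
                                   fcThreshold = 3, pseudocount = 0.01) {
  vn <- if (is(normal, "TranscriptomeCohort")) exprValues(normal)
        else as.matrix(normal)
  vc <- if (is(cancer, "TranscriptomeCohort")) exprValues(cancer)
        else as.matrix(cancer)
  if (nrow(vn) != nrow(vc)) .stopf("gene universes differ between groups")
  if (ncol(vn) < 3L || ncol(vc) < 3L)
    .stopf("each group needs >= 3 samples")
  genes <- rownames(vn) %||% sprintf("g%05d", seq_len(nrow(vn)))
  U <- p <- numeric(nrow(vn))
  for (i in seq_len(nrow(vn))) {
    wt <- suppressWarnings(
      wilcox.test(vc[i, ], vn[i, ], alternative = "two.sided",
                  exact = FALSE, correct = TRUE))
    U[i] <- unname(wt$statistic)
    p[i] <- wt$p.value
  }
  p[!is.finite(p)] <- 1
  fdr <- p.adjust(p, method = "BH")
  mn <- apply(2^vn - 1, 1L, median) + pseudocount
  mc <- apply(2^vc - 1, 1L, median) + pseudocount
  fold <- pmax(mc, mn) / pmin(mc, mn)
  data.frame(gene = genes, U = U, p = p, fdr = fdr, fold = fold,
             direction = ifelse(mc >= mn, "up", "down"),
             pass = fdr <= fdrThreshold & fold >= fcThreshold,
             stringsAsFactors = FALSE)
}

#' Fold enrichment of an annotation within a gene set
#'
#' Compares the observed number of annotated genes in a set against the
#' expectation under random sampling from the universe:
#' `expected = |set| * |annotation| / |universe|`, `fold = observed /
#' expected` (NA when the expectation is 0). The expectation equals the
#' hypergeometric mean.
#'
#' @param geneSet,annotation character vectors of gene IDs, both subsets
#'   of `universe`.
#' @param universe character vector of all gene IDs.
#' @return `list(observed, expected, fold)`.
#' @export
enrichmentFold <- function(geneSet, annotation, universe) {
  if (!length(universe)) .stopf("empty universe")
  geneSet <- intersect(unique(geneSet), universe)
  annotation <- intersect(unique(annotation), universe)
  observed <- length(intersect(geneSet, annotation))
  expected <- length(geneSet) * length(annotation) / length(universe)
  list(observed = observed, expected = expected,
       fold = if (expected > 0) observed / expected else NA_real_)
}

#' Shared top contributing genes per group
#'
#' A gene is a shared top contributing gene of a group (e.g. a cancer
#' type) if it appears in the sample-level top-k lists of at least
#' `minSamples` samples of that group.
#'
#' @param topLists named list of per-sample top-k gene-ID vectors (from
#'   [topContributingGenes()] at sample level).
#' @param groups named character vector mapping sample id -> group label.
#' @param minSamples minimum number of supporting samples (default 2).
#' @return Named list: group -> character vector of gene IDs.
#' @export
sharedTopGenes <- function(topLists, groups, minSamples = 2L) {
  if (is.null(names(topLists)))
    .stopf("'topLists' must be named by sample id")
  missing <- setdiff(names(topLists), names(groups))
  if (length(missing))
    .stopf("no group label for sample '%s'", missing[1L])
  out <- lapply(split(names(topLists), groups[names(topLists)]),
                function(ids) {
    counts <- table(unlist(topLists[ids], use.names = FALSE))
    sort(names(counts)[counts >= minSamples])
  })
  out
}

#' Expression status of top contributing genes
#'
#' For each top-gene list, reports overlap fractions with the top-k
#' expressed genes (by median log2(TPM+1) across the cohort), with
#' tissue-enhanced genes and with housekeeping genes, plus the Spearman
#' correlation between contribution scores and expression levels.
#'
#' @param topLists named list of top-k gene-ID vectors (typically one per
#'   (tissue, explainer) configuration).
#' @param cohort the [TranscriptomeCohort-class] the scores refer to.
#' @param tsSets optional list of tissue-enhanced gene sets (from
#'   [tissueSpecificGenes()]); when the name of a top list matches a
#'   tissue, that tissue's set is used, otherwise the union.
#' @param hkSet optional housekeeping gene set.
#' @param scoreVectors optional named list of full score vectors parallel
#'   to `topLists`, used for the score-vs-expression Spearman correlation.
#' @param summary summary statistic of expression across samples:
#'   `"median"` (default) or `"mean"`.
#' @return data.frame with one row per top list.
#' @export
expressionOverlapReport <- function(topLists, cohort, tsSets = NULL,
                                    hkSet = NULL, scoreVectors = NULL,
                                    summary = c("median", "mean")) {
  summary <- match.arg(summary)
  v <- exprValues(cohort)
  expr <- if (summary == "median") apply(v, 1L, median) else rowMeans(v)
  k <- length(topLists[[1L]])
  topExpressed <- topGenes(expr, k)
  tsUnion <- if (!is.null(tsSets)) unique(unlist(tsSets))
  rows <- lapply(seq_along(topLists), function(i) {
    tl <- topLists[[i]]
    nm <- names(topLists)[i] %||% sprintf("list%02d", i)
    tsRef <- if (is.null(tsSets)) NULL
             else if (nm %in% names(tsSets)) tsSets[[nm]] else tsUnion
    sp <- if (!is.null(scoreVectors))
      spearmanScore(scoreVectors[[i]], expr[names(scoreVectors[[i]])])
    else NA_real_
    data.frame(
      list = nm,
      topExpressedOverlap = length(intersect(tl, topExpressed)) / k,
      tsOverlap = if (is.null(tsRef)) NA_real_
                  else length(intersect(tl, tsRef)) / k,
      hkOverlap = if (is.null(hkSet)) NA_real_
                  else length(intersect(tl, hkSet)) / k,
      spearmanVsExpression = sp,
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recall of planted marker genes in top contributing genes
#'
#' Convenience scorer for synthetic cohorts: the fraction of each tissue's
#' planted markers recovered in that tissue's top-k list.
#'
#' @param topLists named list tissue -> top-k gene IDs.
#' @param truth ground truth from [generateCohort()] (`groundTruth(x)`).
#' @return Named numeric vector of per-tissue recalls.
#' @export
markerRecall <- function(topLists, truth) {
  tissues <- intersect(names(topLists), names(truth$markers))
  if (!length(tissues)) .stopf("no tissue names shared with ground truth")
  vapply(tissues, function(t)
    mean(truth$markers[[t]] %in% topLists[[t]]), numeric(1))
}
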