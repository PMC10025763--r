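#' Design of a synthetic transcriptome cohort
#'
#' Describes a cohort with the statistical structure the downstream analysis
#' assumes: several tissue classes, tissue-enhanced marker genes,
#' housekeeping (HK) genes with stable expression, optional paired cancer
#' classes with planted fold changes, and Gaussian noise on the log2(TPM+1)
#' scale.
#'
#' @param nTissues number of normal tissue classes.
#' @param nSamplesPerTissue samples per tissue; scalar or a vector of length
#'   `nTissues` (unequal counts exercise the up-sampling logic in training).
#' @param nGenes total number of genes.
#' @param nMarkersPerTissue planted tissue-enhanced markers per tissue.
#' @param markerEffect fold change (> 1) applied to a marker's TPM+1
#'   pseudo-abundance in its own tissue, i.e. an additive shift of
#'   `log2(markerEffect)` on the modelling scale.
#' @param nHkGenes number of housekeeping genes.
#' @param hkLevel TPM level of housekeeping genes in every tissue.
#' @param noiseSd standard deviation of Gaussian noise on the log2 scale.
#' @param cancerFraction fraction of tissues given a paired cancer class.
#' @param nDeGenesPerCancer planted differentially expressed genes per
#'   cancer class.
#' @param deEffect TPM-scale fold change (>= 1) of planted DE genes;
#'   alternating genes are up- and down-regulated in cancer.
#' @param baselineMeanlog,baselineSdlog location/scale of the log-normal
#'   background TPM distribution.
#' @param seed integer driving a hierarchical seeding scheme; the emitted
#'   matrix is a deterministic function of the design.
#' @return A list of class `"SyntheticDesign"`.
#' @export
syntheticDesign <- function(nTissues = 3L, nSamplesPerTissue = 50L,
                            nGenes = 800L, nMarkersPerTissue = 20L,
                            markerEffect = 8, nHkGenes = 50L, hkLevel = 20,
                            noiseSd = 0.3, cancerFraction = 0,
                            nDeGenesPerCancer = 30L, deEffect = 8,
                            baselineMeanlog = log(10), baselineSdlog = 1.2,
                            seed = 1L) {
  .assertCount(nTissues, "nTissues", 2L)
  .assertCount(nSamplesPerTissue, "nSamplesPerTissue", 2L)
  .assertCount(nGenes, "nGenes")
  .assertCount(nMarkersPerTissue, "nMarkersPerTissue", 0L)
  .assertCount(nHkGenes, "nHkGenes", 0L)
  .assertCount(nDeGenesPerCancer, "nDeGenesPerCancer", 0L)
  if (markerEffect <= 1) .stopf("'markerEffect' must be > 1")
  if (deEffect < 1) .stopf("'deEffect' must be >= 1")
  if (noiseSd < 0) .stopf("'noiseSd' must be >= 0")
  if (cancerFraction < 0 || cancerFraction > 1)
    .stopf("'cancerFraction' must be in [0, 1]")
  if (length(nSamplesPerTissue) == 1L)
    nSamplesPerTissue <- rep(as.integer(nSamplesPerTissue), nTissues)
  if (length(nSamplesPerTissue) != nTissues)
    .stopf("'nSamplesPerTissue' must be scalar or length nTissues")
  nCancer <- as.integer(round(cancerFraction * nTissues))
  budget <- nMarkersPerTissue * nTissues + nHkGenes +
    nDeGenesPerCancer * nCancer
  if (budget > nGenes)
    .stopf(paste0("infeasible design: markers + HK + DE genes (%d) exceed ",
                  "nGenes (%d)"), budget, nGenes)
  structure(list(
    nTissues = as.integer(nTissues),
    nSamplesPerTissue = as.integer(nSamplesPerTissue),
    nGenes = as.integer(nGenes),
    nMarkersPerTissue = as.integer(nMarkersPerTissue),
    markerEffect = markerEffect, nHkGenes = as.integer(nHkGenes),
    hkLevel = hkLevel, noiseSd = noiseSd, cancerFraction = cancerFraction,
    nCancer = nCancer, nDeGenesPerCancer = as.integer(nDeGenesPerCancer),
    deEffect = deEffect, baselineMeanlog = baselineMeanlog,
    baselineSdlog = baselineSdlog, seed = as.integer(seed)),
    class = "SyntheticDesign")
}

#' @export
print.SyntheticDesign <- function(x, ...) {
  cat(sprintf(
    "SyntheticDesign: %d tissues (+%d cancer), %d genes, noise sd %.2f\n",
    x$nTissues, x$nCancer, x$nGenes, x$noiseSd))
  invisible(x)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Baseline TPM is drawn per gene from a log-normal background. Marker genes
#' have their TPM+1 pseudo-abundance multiplied by `markerEffect` in their
#' own tissue only (an exact `log2(markerEffect)` shift on the modelling
#' scale). HK genes sit at `hkLevel` TPM in all tissues. Each cancer class
#' copies its paired normal tissue and multiplies planted DE genes' TPM by
#' `deEffect` (up) or `1/deEffect` (down), so the realized TPM-scale fold
#' equals `deEffect` exactly in the noise-free profile. Gaussian noise with
#' `noiseSd` is added on the log2 scale and clipped at 0.
#'
#' Marker and DE genes have their baseline TPM floored at 10 so planted fold
#' changes are not dominated by the +1 pseudo-count.
#'
#' @param design a [syntheticDesign()].
#' @return A [TranscriptomeCohort-class]; `groundTruth(x)` holds
#'   `markers` (tissue -> gene ids), `hkGenes`, and `deGenes`
#'   (cancer class -> data.frame(gene, direction, fold)).
#' @export
generateCohort <- function(design) {
  stopifnot(inherits(design, "SyntheticDesign"))
  d <- design
  geneIds <- sprintf("g%05d", seq_len(d$nGenes))
  perm <- .withSeed(deriveSeed(d$seed, 1), sample.int(d$nGenes))

  idx <- 1L
  take <- function(n) {
    out <- perm[seq.int(idx, length.out = n)]
    idx <<- idx + n
    out
  }
  markers <- lapply(seq_len(d$nTissues), function(i) take(d$nMarkersPerTissue))
  hk <- take(d$nHkGenes)
  deIdx <- lapply(seq_len(d$nCancer), function(i) take(d$nDeGenesPerCancer))

  baseTpm <- .withSeed(deriveSeed(d$seed, 2),
                       rlnorm(d$nGenes, d$baselineMeanlog, d$baselineSdlog))
  planted <- c(unlist(markers), unlist(deIdx))
  baseTpm[planted] <- pmax(baseTpm[planted], 10)

  baseLog <- log2(baseTpm + 1)
  tissues <- sprintf("tissue%02d", seq_len(d$nTissues))
  cancers <- if (d$nCancer > 0) sprintf("cancer%02d", seq_len(d$nCancer))
             else character()

  profiles <- matrix(baseLog, nrow = d$nGenes,
                     ncol = d$nTissues + d$nCancer)
  colnames(profiles) <- c(tissues, cancers)
  for (i in seq_len(d$nTissues)) {
    profiles[markers[[i]], i] <- profiles[markers[[i]], i] +
      log2(d$markerEffect)
    profiles[hk, i] <- log2(d$hkLevel + 1)
  }
  deTruth <- list()
  for (j in seq_len(d$nCancer)) {
    col <- d$nTissues + j
    profiles[, col] <- profiles[, j]  # copy the paired normal tissue
    g <- deIdx[[j]]
    dirs <- rep_len(c("up", "down"), length(g))
    tpm <- 2^profiles[g, col] - 1
    tpm <- ifelse(dirs == "up", tpm * d$deEffect, tpm / d$deEffect)
    profiles[g, col] <- log2(tpm + 1)
    deTruth[[cancers[j]]] <- data.frame(
      gene = geneIds[g], direction = dirs, fold = d$deEffect,
      stringsAsFactors = FALSE)
  }

  nPerClass <- c(d$nSamplesPerTissue,
                 if (d$nCancer > 0) d$nSamplesPerTissue[seq_len(d$nCancer)])
  classes <- colnames(profiles)
  blocks <- vector("list", length(classes))
  labels <- character()
  for (k in seq_along(classes)) {
    n <- nPerClass[k]
    noise <- if (d$noiseSd > 0)
      .withSeed(deriveSeed(d$seed, 3, k),
                matrix(rnorm(d$nGenes * n, 0, d$noiseSd), d$nGenes, n))
    else matrix(0, d$nGenes, n)
    blocks[[k]] <- pmax(profiles[, k] + noise, 0)
    labels <- c(labels, rep(classes[k], n))
  }
  values <- do.call(cbind, blocks)
  sampleIds <- sprintf("%s_s%03d", labels,
                       unlist(lapply(nPerClass, seq_len)))
  colnames(values) <- sampleIds
  rownames(values) <- geneIds

  gt <- list(
    markers = stats::setNames(lapply(markers, function(g) geneIds[g]),
                              tissues),
    hkGenes = geneIds[hk],
    deGenes = deTruth,
    pairedNormal = if (d$nCancer > 0)
      stats::setNames(tissues[seq_len(d$nCancer)], cancers) else NULL,
    design = d)
  TranscriptomeCohort(values, labels, geneIds, sampleIds, groundTruth = gt)
}

#' Stratified train/test split
#'
#' Partitions samples within each tissue class at the given ratio (the
#' training fraction), mirroring a 9:1 random partition when `ratio = 0.9`.
#' Partitions are disjoint and exhaustive.
#'
#' @param cohort a [TranscriptomeCohort-class].
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return `list(train =, test =)` of two cohorts.
#' @export
splitTrainTest <- function(cohort, ratio = 0.9, seed = 1L) {
  if (ratio <= 0 || ratio >= 1) .stopf("'ratio' must be in (0, 1)")
  labels <- tissueLabels(cohort)
  tab <- table(labels)
  small <- names(tab)[tab < 2L]
  if (length(small))
    .stopf("class '%s' has fewer than 2 samples and cannot be split",
           small[1L])
  trainIdx <- integer()
  for (cl in sort(names(tab))) {
    who <- which(labels == cl)
    n <- length(who)
    nTrain <- min(n - 1L, max(1L, as.integer(round(ratio * n))))
    pick <- .withSeed(deriveSeed(seed, match(cl, sort(names(tab)))),
                      sample(who, nTrain))
    trainIdx <- c(trainIdx, pick)
  }
  trainIdx <- sort(trainIdx)
  testIdx <- setdiff(seq_along(labels), trainIdx)
  list(train = cohort[, trainIdx], test = cohort[, testIdx])
}
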