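.pipelineDefaults <- function() {
  list(
    seed = 1L,
    design = list(),                 # syntheticDesign() arguments
    models = list(n = 4L, arch = "MLP", hiddenUnits = 64L,
                  maxEpochs = 25L),
    reference = list(kind = "universal", poolSize = 100L),
    explainers = "DeepLift",
    nReferences = 10L,
    protocol = list(nGrid = c(1L, 2L, 4L)),
    genes = list(k = 100L, tsFold = 5, minTpm = 1, fdr = 0.001, fc = 3),
    annotationFile = NULL,
    maxSamplesPerTissue = 5L)
}

.mergeConfig <- function(defaults, user) {
  for (nm in names(user)) {
    defaults[[nm]] <- if (is.list(defaults[[nm]]) && is.list(user[[nm]]))
      .mergeConfig(defaults[[nm]], user[[nm]]) else user[[nm]]
  }
  defaults
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    .stopf("[stage %s] %s", name, conditionMessage(e)))
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> split -> train -> explain -> aggregate ->
#' gene-level reports on a synthetic cohort, writing all intermediates and
#' reports (TSV/CSV/JSON) plus a manifest into `outdir`. Rerunning with the
#' same configuration reproduces the deterministic outputs.
#'
#' @param config nested list overriding the defaults (seed, `design` =
#'   [syntheticDesign()] arguments, `models` (n, arch, hiddenUnits,
#'   maxEpochs), `reference` (kind, poolSize), `explainers`, `nReferences`,
#'   `protocol$nGrid`, `genes` thresholds, optional `annotationFile`), or
#'   the path of a YAML file holding that list.
#' @param outdir output directory (created if missing).
#' @return Invisibly, a list with the run manifest and the main in-memory
#'   results (models, top lists, reports).
#' @export
runPipeline <- function(config = list(), outdir = tempfile("xplainrun")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.pipelineDefaults(), config)
  if (!is.null(cfg$annotationFile) && !file.exists(cfg$annotationFile))
    .stopf("[stage config] annotation file '%s' not found",
           cfg$annotationFile)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(f) { files <<- c(files, f); f }

  design <- .stage("simulate",
                   do.call(syntheticDesign,
                           c(cfg$design,
                             if (is.null(cfg$design$seed))
                               list(seed = deriveSeed(cfg$seed, 1)))))
  cohort <- .stage("simulate", generateCohort(design))
  writeCohortTSV(cohort, put(file.path(outdir, "cohort.tsv")),
                 put(file.path(outdir, "cohort.labels.tsv")))
  writeGroundTruthJSON(groundTruth(cohort),
                       put(file.path(outdir, "ground_truth.json")))

  split <- .stage("split", splitTrainTest(cohort, 0.9,
                                          seed = deriveSeed(cfg$seed, 2)))
  nCls <- length(unique(tissueLabels(cohort)))
  models <- .stage("train", lapply(seq_len(cfg$models$n), function(j) {
    mc <- modelConfig(cfg$models$arch, nGenes = nrow(cohort),
                      nClasses = nCls,
                      hiddenUnits = cfg$models$hiddenUnits,
                      maxEpochs = cfg$models$maxEpochs,
                      seed = deriveSeed(cfg$seed, 3, j))
    trainClassifier(buildModel(mc, geneIds = rownames(cohort)),
                    split$train)
  }))
  histAll <- do.call(rbind, lapply(seq_along(models), function(j)
    cbind(model = j, models[[j]]@history)))
  write.table(histAll, put(file.path(outdir, "training_history.csv")),
              sep = ",", quote = FALSE, row.names = FALSE)
  testAcc <- mean(predictClass(models[[1L]], split$test) ==
                    tissueLabels(split$test))

  stats <- geneStats(cohort)
  spec <- referenceSpec(cfg$reference$kind,
                        poolSize = cfg$reference$poolSize,
                        seed = deriveSeed(cfg$seed, 4))
  pool <- .stage("references",
                 buildReferencePool(spec, stats = if (spec$kind %in%
                     c("universal", "specific")) stats else NULL,
                   nGenes = nrow(cohort)))

  needsRef <- cfg$explainers %in% c("DeepLift", "DeepLiftShap",
                                    "IntegratedGradients")
  evalLabels <- tissueLabels(split$test)
  keep <- unlist(lapply(split(seq_along(evalLabels), evalLabels),
                        head, cfg$maxSamplesPerTissue))
  evalSet <- split$test[, sort(keep)]
  X <- t(exprValues(evalSet))
  evalLabels <- tissueLabels(evalSet)

  topLists <- list(); scoreMats <- list()
  .stage("explain", for (ex in cfg$explainers) {
    sm <- matrix(0, nrow(X), ncol(X),
                 dimnames = list(rownames(X), colnames(X)))
    for (s in seq_len(nrow(X))) {
      acc <- numeric(ncol(X))
      for (j in seq_along(models))
        acc <- acc + .attrScores(
          models[[j]], X[s, ], ex, evalLabels[s],
          referencePool = if (ex %in% c("DeepLift", "DeepLiftShap",
                                        "IntegratedGradients")) pool,
          nReferences = cfg$nReferences, dropoutEnabled = TRUE,
          seed = deriveSeed(cfg$seed, 5, j, s))
      sm[s, ] <- acc / length(models)
    }
    scoreMats[[ex]] <- sm
    topLists[[ex]] <- topContributingGenes(sm, "tissue", cfg$genes$k,
                                           tissueLabels = evalLabels)
    for (t in names(topLists[[ex]]))
      writeAttributionTSV(
        stats::setNames(colMeans(sm[evalLabels == t, , drop = FALSE]),
                        colnames(sm)),
        put(file.path(outdir, sprintf("attribution_%s_%s.tsv", ex, t))))
  })

  proto <- .stage("protocol", aggregationProtocol(
    X[1L, ], models, cfg$explainers[[1L]], evalLabels[1L],
    nGrid = cfg$protocol$nGrid, k = cfg$genes$k,
    referencePool = if (needsRef[[1L]]) pool,
    nReferences = cfg$nReferences,
    seed = deriveSeed(cfg$seed, 6)))
  write.table(proto$curve, put(file.path(outdir, "protocol_curve.csv")),
              sep = ",", quote = FALSE, row.names = FALSE)

  geneReport <- .stage("genes", {
    hk <- housekeepingGenes(cohort)
    ts <- tissueSpecificGenes(cohort, cfg$genes$tsFold, cfg$genes$minTpm)
    truth <- groundTruth(cohort)
    recall <- lapply(topLists, markerRecall, truth = truth)
    de <- if (length(truth$deGenes)) {
      cl <- names(truth$deGenes)[1L]
      nl <- truth$pairedNormal[[cl]]
      differentialExpression(
        cohort[, tissueLabels(cohort) == nl],
        cohort[, tissueLabels(cohort) == cl],
        fdrThreshold = cfg$genes$fdr, fcThreshold = cfg$genes$fc)
    }
    enr <- if (!is.null(cfg$annotationFile)) {
      anno <- readGeneList(cfg$annotationFile)
      lapply(topLists[[1L]], enrichmentFold, annotation = anno,
             universe = rownames(cohort))
    }
    overlap <- expressionOverlapReport(topLists[[1L]], cohort,
                                       tsSets = ts, hkSet = hk)
    if (!is.null(de))
      write.table(de, put(file.path(outdir, "de_genes.tsv")), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    write.table(overlap, put(file.path(outdir, "expression_overlap.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(hk = hk, ts = ts, markerRecall = recall, de = de,
         enrichment = enr, overlap = overlap)
  })

  manifest <- list(
    package = as.character(utils::packageVersion("transXplain")),
    seed = cfg$seed, configHash = .configHash(deparse(cfg)),
    testAccuracyModel1 = testAcc,
    markerRecall = lapply(geneReport$markerRecall, as.list),
    files = basename(files))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, outdir = outdir, models = models,
                 topLists = topLists, protocol = proto,
                 genes = geneReport, cohort = cohort))
}
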