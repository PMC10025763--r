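# Shared fixtures, all generated in code.

# cohort whose per-tissue medians are exact: `medianTpm` is a genes x
# tissues matrix of TPM medians; each tissue gets `n` identical samples.
constantCohort <- function(medianTpm, n = 3L) {
  tissues <- colnames(medianTpm) %||%
    sprintf("tissue%02d", seq_len(ncol(medianTpm)))
  v <- do.call(cbind, lapply(seq_len(ncol(medianTpm)), function(j)
    matrix(log2(medianTpm[, j] + 1), nrow(medianTpm), n)))
  labels <- rep(tissues, each = n)
  colnames(v) <- sprintf("%s_s%d", labels, rep(seq_len(n), ncol(medianTpm)))
  rownames(v) <- rownames(medianTpm) %||%
    sprintf("g%05d", seq_len(nrow(medianTpm)))
  TranscriptomeCohort(v, labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a dense-only (purely linear) classifier: score_j = x . W[, j] + b[j]
linearModel <- function(W, b = numeric(ncol(W)),
                        classes = as.character(seq_len(ncol(W)))) {
  cfg <- modelConfig("MLP", nGenes = nrow(W), nClasses = ncol(W),
                     dropoutP = 0)
  m <- buildModel(cfg)
  m@layers <- list(list(type = "dense", W = W, b = b))
  m@classLevels <- classes
  m@trained <- TRUE
  m
}

# freshly initialized small ReLU MLP marked usable for explanation
randomReluMlp <- function(nGenes, hidden, nClasses, seed,
                          dropoutP = 0) {
  cfg <- modelConfig("MLP", nGenes = nGenes, nClasses = nClasses,
                     hiddenUnits = hidden, dropoutP = dropoutP,
                     seed = seed)
  m <- buildModel(cfg)
  m@classLevels <- as.character(seq_len(nClasses))
  m@trained <- TRUE
  m
}

# pre-softmax score of one class, computed by a plain forward pass
modelScore <- function(model, x, classIdx) {
  transXplain:::.modelForward(model, matrix(x, 1L))$scores[1L, classIdx]
}

# central finite-difference gradient of the class score (float64 oracle)
fdGradient <- function(model, x, classIdx, h = 1e-4) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h
    xm[i] <- xm[i] - h
    (modelScore(model, xp, classIdx) - modelScore(model, xm, classIdx)) /
      (2 * h)
  }, numeric(1))
}

# small trained MLP ensemble on a shared synthetic cohort
trainToyEnsemble <- function(nModels = 3L, nGenes = 300L, nTissues = 3L,
                             nSamples = 40L, noiseSd = 0.3,
                             hidden = 48L, epochs = 40L, seed = 11L) {
  d <- syntheticDesign(nTissues = nTissues, nSamplesPerTissue = nSamples,
                       nGenes = nGenes,
                       nMarkersPerTissue = max(5L, nGenes %/% 40L),
                       markerEffect = 8, nHkGenes = nGenes %/% 16L,
                       noiseSd = noiseSd, seed = seed)
  co <- generateCohort(d)
  sp <- splitTrainTest(co, 0.9, seed = seed)
  models <- lapply(seq_len(nModels), function(j) {
    cfg <- modelConfig("MLP", nGenes = nGenes, nClasses = nTissues,
                       hiddenUnits = hidden, maxEpochs = epochs,
                       seed = seed * 100L + j)
    trainClassifier(buildModel(cfg, rownames(co)), sp$train)
  })
  list(cohort = co, split = sp, models = models)
}
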