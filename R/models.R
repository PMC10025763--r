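#' Configuration of an MLP or CNN tissue classifier
#'
#' The MLP has a single hidden layer (default 128 units) with batch
#' normalization and ReLU, and dropout before the output layer. The CNN
#' stacks three convolutional stages (conv -> max-pool(2) -> batch norm ->
#' ReLU), dropout, global average pooling (followed by batch norm and ReLU),
#' and a fully connected output layer; its input is the gene-expression
#' vector placed row-major, in `geneOrder`, into a `gridSide x gridSide`
#' matrix with zero padding at the bottom.
#'
#' @param arch "MLP" or "CNN".
#' @param nGenes,nClasses input and output dimensions.
#' @param hiddenUnits MLP hidden-layer width (default 128).
#' @param channels CNN channel counts for the three convolutional stages,
#'   the global-average-pooling stage, and the output layer; defaults to
#'   `c(64, 128, 256, 256, nClasses)`. The fourth entry must equal the third
#'   and the fifth must equal `nClasses`.
#' @param kernelSizes CNN convolution kernel sizes (default `c(5, 5, 3)`).
#' @param poolKernel max-pooling kernel (default 2).
#' @param gridSide CNN grid side; default is the smallest integer whose
#'   square holds `nGenes`.
#' @param dropoutP dropout probability (default 0.25).
#' @param lr initial Adam learning rate; defaults to 0.001 for MLP and
#'   0.0006 for CNN.
#' @param l2Lambda L2 regularization strength on dense/conv weights
#'   (default 0.001).
#' @param batchSize mini-batch size (default 256).
#' @param lrPatience epochs without loss improvement before the learning
#'   rate is reduced (default 5).
#' @param lrFactor multiplicative learning-rate reduction (default 0.25).
#' @param maxEpochs training epochs.
#' @param seed integer seed driving initialization, up-sampling, shuffling
#'   and dropout.
#' @param geneOrder permutation of `seq_len(nGenes)` controlling CNN grid
#'   placement; default identity.
#' @return A list of class `"ModelConfig"`.
#' @export
modelConfig <- function(arch = c("MLP", "CNN"), nGenes, nClasses,
                        hiddenUnits = 128L, channels = NULL,
                        kernelSizes = c(5L, 5L, 3L), poolKernel = 2L,
                        gridSide = NULL, dropoutP = 0.25, lr = NULL,
                        l2Lambda = 0.001, batchSize = 256L, lrPatience = 5L,
                        lrFactor = 0.25, maxEpochs = 30L, seed = 1L,
                        geneOrder = NULL) {
  arch <- match.arg(arch)
  .assertCount(nGenes, "nGenes")
  .assertCount(nClasses, "nClasses", 2L)
  if (dropoutP < 0 || dropoutP >= 1) .stopf("'dropoutP' must be in [0, 1)")
  if (is.null(lr)) lr <- if (arch == "CNN") 0.0006 else 0.001
  if (lr <= 0) .stopf("'lr' must be > 0")
  if (is.null(gridSide)) gridSide <- as.integer(ceiling(sqrt(nGenes)))
  if (gridSide^2 < nGenes)
    .stopf("gridSide^2 (%d) must hold all %d genes", gridSide^2, nGenes)
  if (is.null(channels)) channels <- c(64L, 128L, 256L, 256L, nClasses)
  if (arch == "CNN") {
    if (length(channels) != 5L || channels[4L] != channels[3L] ||
        channels[5L] != nClasses)
      .stopf(paste0("'channels' must be length 5 with channels[4] == ",
                    "channels[3] and channels[5] == nClasses"))
    if (length(kernelSizes) != 3L) .stopf("'kernelSizes' must be length 3")
  }
  if (is.null(geneOrder)) geneOrder <- seq_len(nGenes)
  if (length(geneOrder) != nGenes || anyDuplicated(geneOrder) ||
      any(sort(geneOrder) != seq_len(nGenes)))
    .stopf("'geneOrder' must be a permutation of seq_len(nGenes)")
  structure(list(
    arch = arch, nGenes = as.integer(nGenes),
    nClasses = as.integer(nClasses), hiddenUnits = as.integer(hiddenUnits),
    channels = as.integer(channels), kernelSizes = as.integer(kernelSizes),
    poolKernel = as.integer(poolKernel), gridSide = as.integer(gridSide),
    dropoutP = dropoutP, lr = lr, l2Lambda = l2Lambda,
    batchSize = as.integer(batchSize), lrPatience = as.integer(lrPatience),
    lrFactor = lrFactor, maxEpochs = as.integer(maxEpochs),
    seed = as.integer(seed), geneOrder = as.integer(geneOrder)),
    class = "ModelConfig")
}

#' Place a gene-expression vector on the CNN input grid
#'
#' Genes are placed row-major, in `config$geneOrder`, into a
#' `gridSide x gridSide` matrix; trailing cells are zero padding. The
#' inverse mapping ([flattenFromGrid()]) recovers the vector exactly.
#'
#' @param sample numeric vector of length `config$nGenes`.
#' @param config a [modelConfig()].
#' @return A `gridSide x gridSide` numeric matrix.
#' @export
reshapeToGrid <- function(sample, config) {
  if (length(sample) != config$nGenes)
    .stopf("expected %d gene values, got %d", config$nGenes, length(sample))
  S <- config$gridSide
  v <- c(sample[config$geneOrder], numeric(S * S - config$nGenes))
  matrix(v, S, S, byrow = TRUE)
}

#' @rdname reshapeToGrid
#' @param grid a matrix produced by [reshapeToGrid()].
#' @export
flattenFromGrid <- function(grid, config) {
  v <- as.vector(t(grid))[seq_len(config$nGenes)]
  out <- numeric(config$nGenes)
  out[config$geneOrder] <- v
  out
}

# column permutation mapping row-major grid filling onto R's column-major
# array layout (see .layerForward "togrid")
.rowMajorColperm <- function(S) {
  k <- seq_len(S * S)
  ((k - 1L) %% S) * S + ((k - 1L) %/% S) + 1L
}

#' Build an (untrained) tissue classifier
#'
#' Parameter initialization is fan-in-scaled Gaussian (He initialization for
#' ReLU stages), seeded by `config$seed`; two builds with the same
#' configuration are identical.
#'
#' @param config a [modelConfig()].
#' @param geneIds optional gene identifiers (length `nGenes`).
#' @return An untrained [TissueClassifier-class].
#' @export
buildModel <- function(config, geneIds = NULL) {
  stopifnot(inherits(config, "ModelConfig"))
  if (is.null(geneIds)) geneIds <- sprintf("g%05d", seq_len(config$nGenes))
  layers <- .withSeed(deriveSeed(config$seed, 10), {
    if (config$arch == "MLP") {
      list(.lyDense(config$nGenes, config$hiddenUnits),
           .lyBnorm(config$hiddenUnits),
           list(type = "relu"),
           c(list(type = "dropout", p = config$dropoutP),
             list(maskDim = config$hiddenUnits)),
           .lyDense(config$hiddenUnits, config$nClasses))
    } else {
      S <- config$gridSide
      colperm <- .rowMajorColperm(S)
      ly <- list(list(type = "togrid", side = S,
                      geneOrder = config$geneOrder, colperm = colperm,
                      invcolperm = order(colperm)))
      H <- S; cin <- 1L
      for (s in 1:3) {
        k <- config$kernelSizes[s]
        cout <- config$channels[s]
        H <- H - k + 1L
        if (H < 1L)
          .stopf("grid side %d too small for convolution stage %d", S, s)
        ly <- c(ly, list(.lyConv(k, k, cin, cout)))
        H <- H %/% config$poolKernel
        if (H < 1L)
          .stopf("grid side %d too small for pooling at stage %d", S, s)
        ly <- c(ly, list(list(type = "maxpool", k = config$poolKernel),
                         .lyBnorm(cout, "channel"),
                         list(type = "relu")))
        cin <- cout
      }
      ly <- c(ly,
              list(c(list(type = "dropout", p = config$dropoutP),
                     list(maskDim = c(H, H, cin))),
                   list(type = "gap"),
                   .lyBnorm(cin),
                   list(type = "relu"),
                   .lyDense(cin, config$nClasses)))
      ly
    }
  })
  camLayer <- if (config$arch == "CNN") {
    # the ReLU closing the third convolutional stage
    which(vapply(layers, function(l) l$type, "") == "relu")[3L]
  } else NA_integer_
  cfg <- unclass(config)
  cfg$camLayer <- camLayer
  new("TissueClassifier", arch = config$arch, config = cfg, layers = layers,
      classLevels = character(), geneIds = as.character(geneIds),
      geneOrder = config$geneOrder,
      history = data.frame(), trained = FALSE)
}

#' Equal-count per-class resampling indices for one training epoch
#'
#' Every class is presented with the same number of samples (the size of
#' the largest class); minority classes are up-sampled with replacement,
#' so every original sample has positive selection probability.
#'
#' @param labels per-sample class labels.
#' @param seed integer seed.
#' @return Integer indices into `labels`.
#' @export
upsampleIndices <- function(labels, seed = 1L) {
  tab <- table(labels)
  m <- max(tab)
  .withSeed(seed, {
    idx <- unlist(lapply(sort(names(tab)), function(cl) {
      who <- which(labels == cl)
      if (length(who) == m) who else sample(who, m, replace = TRUE)
    }), use.names = FALSE)
    sample(idx)
  })
}

.softmax <- function(scores) {
  z <- scores - apply(scores, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.adamInit <- function(layers) {
  lapply(layers, function(ly) {
    nm <- intersect(c("W", "b", "gamma", "beta"), names(ly))
    if (!length(nm)) return(NULL)
    stats::setNames(lapply(nm, function(p)
      list(m = ly[[p]] * 0, v = ly[[p]] * 0)), nm)
  })
}

#' Train a tissue classifier
#'
#' Adam on softmax cross-entropy with L2 regularization of dense and
#' convolutional weights. Each epoch presents equal per-class counts via
#' up-sampling with replacement; if the training loss does not improve by
#' more than `1e-4` for `lrPatience` consecutive epochs, the learning rate
#' is multiplied by `lrFactor`. Deterministic given `config$seed` (up to
#' floating-point reduction order).
#'
#' @param model an untrained [buildModel()] result (retraining restarts
#'   Adam but keeps current weights).
#' @param cohort a [TranscriptomeCohort-class] of training samples.
#' @param maxEpochs overrides `config$maxEpochs` when given.
#' @param verbose print per-epoch loss.
#' @return The trained [TissueClassifier-class] with `history` filled in.
#' @export
trainClassifier <- function(model, cohort, maxEpochs = NULL,
                            verbose = FALSE) {
  cfg <- model@config
  labels <- tissueLabels(cohort)
  lv <- sort(unique(labels))
  if (length(lv) < 2L) .stopf("training requires >= 2 classes")
  if (length(lv) != cfg$nClasses)
    .stopf("cohort has %d classes but model expects %d", length(lv),
           cfg$nClasses)
  X <- t(exprValues(cohort))
  if (ncol(X) != cfg$nGenes)
    .stopf("cohort has %d genes but model expects %d", ncol(X), cfg$nGenes)
  if (!all(is.finite(X))) .stopf("training matrix must be finite")
  y <- match(labels, lv)
  nEpochs <- as.integer(maxEpochs %||% cfg$maxEpochs)

  layers <- model@layers
  opt <- .adamInit(layers)
  lr <- cfg$lr
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tAdam <- 0L
  best <- Inf; sinceImp <- 0L
  hist <- vector("list", nEpochs)

  for (ep in seq_len(nEpochs)) {
    epState <- .withSeed(deriveSeed(cfg$seed, 100, ep), {
      idx <- upsampleIndices(labels, deriveSeed(cfg$seed, 200, ep))
      nTot <- length(idx)
      lossSum <- 0; correct <- 0L
      starts <- seq(1L, nTot, by = cfg$batchSize)
      for (st in starts) {
        bi <- idx[st:min(st + cfg$batchSize - 1L, nTot)]
        xb <- X[bi, , drop = FALSE]
        yb <- y[bi]
        mdl <- model; mdl@layers <- layers
        fw <- .modelForward(mdl, xb, mode = "train", keepCache = TRUE)
        layers <- fw$layers
        probs <- .softmax(fw$scores)
        pTrue <- probs[cbind(seq_along(yb), yb)]
        loss <- -mean(log(pmax(pTrue, 1e-300)))
        if (!is.finite(loss))
          .stopf("non-finite training loss at epoch %d (lr=%g)", ep, lr)
        lossSum <- lossSum + loss * length(yb)
        correct <- correct + sum(max.col(probs) == yb)
        dscores <- probs
        dscores[cbind(seq_along(yb), yb)] <-
          dscores[cbind(seq_along(yb), yb)] - 1
        dscores <- dscores / length(yb)
        mdl@layers <- layers
        bw <- .modelBackward(mdl, fw$caches, dscores, paramGrads = TRUE)
        tAdam <- tAdam + 1L
        for (i in seq_along(layers)) {
          pg <- bw$paramGrads[[i]]
          if (is.null(pg)) next
          for (p in names(pg)) {
            g <- pg[[p]]
            if (p == "W" && layers[[i]]$type %in% c("dense", "conv"))
              g <- g + cfg$l2Lambda * layers[[i]][[p]]
            st_ <- opt[[i]][[p]]
            st_$m <- b1 * st_$m + (1 - b1) * g
            st_$v <- b2 * st_$v + (1 - b2) * g^2
            mhat <- st_$m / (1 - b1^tAdam)
            vhat <- st_$v / (1 - b2^tAdam)
            layers[[i]][[p]] <- layers[[i]][[p]] -
              lr * mhat / (sqrt(vhat) + epsA)
            opt[[i]][[p]] <- st_
          }
        }
      }
      list(loss = lossSum / nTot, acc = correct / nTot,
           layers = layers, opt = opt, tAdam = tAdam)
    })
    layers <- epState$layers; opt <- epState$opt; tAdam <- epState$tAdam
    if (epState$loss < best - 1e-4) {
      best <- epState$loss; sinceImp <- 0L
    } else {
      sinceImp <- sinceImp + 1L
      if (sinceImp >= cfg$lrPatience) {
        lr <- lr * cfg$lrFactor
        sinceImp <- 0L
      }
    }
    hist[[ep]] <- data.frame(epoch = ep, loss = epState$loss,
                             accuracy = epState$acc, lr = lr)
    if (verbose)
      message(sprintf("epoch %d: loss %.4f acc %.3f lr %g", ep,
                      epState$loss, epState$acc, lr))
  }
  model@layers <- layers
  model@classLevels <- lv
  model@geneIds <- rownames(cohort)
  model@history <- do.call(rbind, hist)
  model@trained <- TRUE
  model
}

.inputMatrix <- function(model, x) {
  if (is(x, "TranscriptomeCohort")) x <- t(exprValues(x))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  if (ncol(x) != model@config$nGenes)
    .stopf("input has %d genes but model expects %d", ncol(x),
           model@config$nGenes)
  x
}

#' Class probabilities for samples
#'
#' Evaluation-mode forward pass (batch-norm running statistics, dropout
#' off) followed by softmax; rows sum to 1.
#'
#' @param model a trained [TissueClassifier-class].
#' @param x a [TranscriptomeCohort-class], a samples-by-genes matrix, or a
#'   single gene-expression vector.
#' @return Matrix of per-sample class probabilities (columns =
#'   `classLevels(model)`).
#' @export
predictProb <- function(model, x) {
  if (!model@trained) .stopf("model is not trained")
  X <- .inputMatrix(model, x)
  p <- .softmax(.modelForward(model, X)$scores)
  colnames(p) <- model@classLevels
  rownames(p) <- rownames(X)
  p
}

#' @describeIn predictProb predicted class labels (argmax of probability).
#' @export
predictClass <- function(model, x) {
  p <- predictProb(model, x)
  model@classLevels[max.col(p, ties.method = "first")]
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified per tissue, disjoint and exhaustive (per-class fold
#' sizes differ by at most one); metrics are computed on the pooled held-out
#' predictions of all folds.
#'
#' @param cohort a [TranscriptomeCohort-class].
#' @param config a [modelConfig()].
#' @param nFolds number of folds (default 5).
#' @param seed integer seed for fold assignment.
#' @param maxEpochs training epochs per fold (default `config$maxEpochs`).
#' @return `list(accuracy, perClass, predictions, foldAssignment)`.
#' @export
crossValidate <- function(cohort, config, nFolds = 5L, seed = 1L,
                          maxEpochs = NULL) {
  labels <- tissueLabels(cohort)
  tab <- table(labels)
  if (any(tab < nFolds))
    .stopf("class '%s' has fewer samples (%d) than folds (%d)",
           names(tab)[which.min(tab)], min(tab), nFolds)
  fold <- integer(length(labels))
  for (cl in sort(names(tab))) {
    who <- which(labels == cl)
    who <- .withSeed(deriveSeed(seed, 300, match(cl, sort(names(tab)))),
                     sample(who))
    fold[who] <- rep_len(seq_len(nFolds), length(who))
  }
  preds <- character(length(labels))
  for (f in seq_len(nFolds)) {
    cfgF <- config
    cfgF$seed <- deriveSeed(seed, 400, f)
    class(cfgF) <- "ModelConfig"
    mdl <- buildModel(cfgF, geneIds = rownames(cohort))
    mdl <- trainClassifier(mdl, cohort[, fold != f],
                           maxEpochs = maxEpochs)
    preds[fold == f] <- predictClass(mdl, cohort[, fold == f])
  }
  acc <- mean(preds == labels)
  perClass <- vapply(sort(names(tab)), function(cl)
    mean(preds[labels == cl] == cl), numeric(1))
  list(accuracy = acc, perClass = perClass,
       predictions = data.frame(sample = colnames(cohort), truth = labels,
                                predicted = preds, fold = fold,
                                stringsAsFactors = FALSE),
       foldAssignment = fold)
}

# Draw per-unit dropout masks (keep indicators) for every dropout layer.
.drawDropoutMasks <- function(model, seed) {
  masks <- vector("list", length(model@layers))
  for (i in seq_along(model@layers)) {
    ly <- model@layers[[i]]
    if (ly$type != "dropout" || ly$p <= 0) next
    n <- prod(ly$maskDim)
    keep <- .withSeed(deriveSeed(seed, 500, i),
                      as.numeric(runif(n) >= ly$p))
    masks[[i]] <- if (length(ly$maskDim) > 1L) array(keep, ly$maskDim)
                  else keep
  }
  masks
}

.targetIndex <- function(model, targetClass) {
  k <- match(targetClass, model@classLevels)
  if (is.na(k))
    .stopf("unknown class '%s'; model classes: %s", targetClass,
           paste(model@classLevels, collapse = ", "))
  k
}

# gradient of the pre-softmax target-class score w.r.t. each input gene,
# for a batch of inputs; returns an N x nGenes matrix
.gradBatch <- function(model, X, targetIdx, mode = "gradient",
                       masks = NULL) {
  fw <- .modelForward(model, X, mode = "eval", masks = masks,
                      keepCache = TRUE)
  dscores <- matrix(0, nrow(X), model@config$nClasses)
  dscores[, targetIdx] <- 1
  .modelBackward(model, fw$caches, dscores, mode = mode)$grad
}

#' Gradient of a class score with respect to each gene
#'
#' Reverse-mode derivative of the pre-softmax score of `targetClass` with
#' respect to the input expression vector; the foundation of all
#' gradient-based explainers. With `dropoutEnabled`, one dropout mask drawn
#' from `seed` is applied in the forward pass and respected in the backward
#' pass. Batch normalization uses running (evaluation) statistics. For CNN
#' models the gradient is mapped back through the grid to gene order.
#'
#' @param model a trained [TissueClassifier-class].
#' @param sample gene-expression vector.
#' @param targetClass class label whose score is differentiated.
#' @param dropoutEnabled draw and apply a dropout mask (the source of
#'   intra-model attribution variability).
#' @param seed seed for the dropout mask.
#' @return Named numeric per-gene gradient vector.
#' @export
classScoreGradient <- function(model, sample, targetClass,
                               dropoutEnabled = FALSE, seed = 1L) {
  X <- .inputMatrix(model, sample)
  k <- .targetIndex(model, targetClass)
  masks <- if (dropoutEnabled) .drawDropoutMasks(model, seed)
  g <- .gradBatch(model, X, k, masks = masks)
  stats::setNames(as.vector(g), model@geneIds)
}
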