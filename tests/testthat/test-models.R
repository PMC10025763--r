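test_that("grid reshape is row-major, padded, and exactly invertible", {
  cfg <- modelConfig("MLP", nGenes = 9L, nClasses = 2L, gridSide = 3L)
  g <- reshapeToGrid(1:9, cfg)
  expect_equal(g, matrix(1:9, 3, 3, byrow = TRUE), ignore_attr = TRUE)

  cfg10 <- modelConfig("MLP", nGenes = 10L, nClasses = 2L, gridSide = 4L)
  g10 <- reshapeToGrid(1:10, cfg10)
  expect_equal(sum(g10 == 0), 16L - 10L)

  for (s in 1:3) {
    perm <- withr::with_seed(s, sample.int(10L))
    cfgP <- modelConfig("MLP", nGenes = 10L, nClasses = 2L, gridSide = 4L,
                        geneOrder = perm)
    x <- withr::with_seed(s + 10L, rnorm(10))
    expect_equal(flattenFromGrid(reshapeToGrid(x, cfgP), cfgP), x)
  }
  expect_error(reshapeToGrid(1:5, cfg), "gene values")
})

test_that("model building is seeded and matches the closed-form size", {
  cfg <- modelConfig("MLP", nGenes = 200L, nClasses = 4L,
                     hiddenUnits = 128L, seed = 7L)
  m1 <- buildModel(cfg)
  m2 <- buildModel(cfg)
  expect_identical(m1@layers, m2@layers)

  # 200 -> 128 dense (W + b), batch norm (gamma + beta), 128 -> 4 dense
  nPar <- sum(vapply(m1@layers, function(ly)
    sum(lengths(ly[intersect(c("W", "b", "gamma", "beta"), names(ly))])),
    numeric(1)))
  expect_equal(nPar, (200 * 128 + 128) + (128 + 128) + (128 * 4 + 4))

  cfgC <- modelConfig("CNN", nGenes = 200L, nClasses = 3L,
                      channels = c(4L, 8L, 8L, 8L, 3L),
                      kernelSizes = c(3L, 3L, 3L), gridSide = 24L,
                      seed = 7L)
  mc <- buildModel(cfgC)
  mc@classLevels <- c("a", "b", "c"); mc@trained <- TRUE
  sc <- predictProb(mc, numeric(200))
  expect_true(all(is.finite(sc)))

  expect_error(buildModel(modelConfig("CNN", nGenes = 64L, nClasses = 3L,
                                      channels = c(4L, 8L, 8L, 8L, 3L),
                                      kernelSizes = c(5L, 5L, 3L),
                                      gridSide = 8L)),
               "too small")
})

test_that("up-sampling presents equal per-class counts with full support", {
  labels <- c(rep("a", 10L), rep("b", 100L))
  idx <- upsampleIndices(labels, seed = 4L)
  expect_equal(unname(table(labels[idx])), c(100L, 100L),
               ignore_attr = TRUE)
  # every majority-class sample kept; minority support positive
  expect_setequal(unique(idx[labels[idx] == "b"]), 11:110)
  seen <- table(factor(idx[labels[idx] == "a"], levels = 1:10))
  expect_true(all(seen >= 0) && sum(seen) == 100L)
})

test_that("training separates a noise-free cohort and predicts cleanly", {
  fx <- trainToyEnsemble(nModels = 1L, nGenes = 200L, nSamples = 50L,
                         noiseSd = 0, hidden = 32L, epochs = 50L,
                         seed = 21L)
  m <- fx$models[[1L]]
  acc <- mean(predictClass(m, fx$split$test) ==
                tissueLabels(fx$split$test))
  expect_gte(acc, 0.95)

  p <- predictProb(m, fx$split$test)
  expect_lt(max(abs(rowSums(p) - 1)), 1e-6)

  trainAcc <- mean(predictClass(m, fx$split$train) ==
                     tissueLabels(fx$split$train))
  expect_gte(trainAcc, 0.95)

  # evaluation is a pure function: duplicated rows agree, repeats agree
  X <- t(exprValues(fx$split$test))
  p2 <- predictProb(m, rbind(X[1L, ], X[1L, ]))
  expect_equal(p2[1L, ], p2[2L, ])
  expect_identical(predictProb(m, X), predictProb(m, X))

  expect_error(predictProb(m, numeric(10L)), "genes")
})

test_that("plateaued training loss triggers the learning-rate schedule", {
  d <- syntheticDesign(nTissues = 2L, nSamplesPerTissue = 10L,
                       nGenes = 40L, nMarkersPerTissue = 2L,
                       nHkGenes = 4L, noiseSd = 0.2, seed = 2L)
  co <- generateCohort(d)
  # a vanishing learning rate freezes the loss, so reductions fire every
  # `lrPatience` epochs: multiply-by-lrFactor, not subtract
  cfg <- modelConfig("MLP", nGenes = 40L, nClasses = 2L, hiddenUnits = 8L,
                     lr = 1e-12, lrPatience = 2L, lrFactor = 0.25,
                     maxEpochs = 6L, seed = 2L)
  m <- trainClassifier(buildModel(cfg, rownames(co)), co)
  expect_equal(m@history$lr,
               1e-12 * c(1, 1, 0.25, 0.25, 0.0625, 0.0625))
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  fx <- trainToyEnsemble(nModels = 0L, nGenes = 150L, nSamples = 25L,
                         noiseSd = 0, seed = 31L)
  cfg <- modelConfig("MLP", nGenes = 150L, nClasses = 3L,
                     hiddenUnits = 24L, maxEpochs = 80L, seed = 31L)
  cv <- crossValidate(fx$cohort, cfg, nFolds = 5L, seed = 8L)
  labels <- tissueLabels(fx$cohort)
  for (t in unique(labels)) {
    sizes <- table(cv$foldAssignment[labels == t])
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_equal(sort(unique(cv$foldAssignment)), 1:5)
  expect_length(cv$foldAssignment, ncol(fx$cohort))
  expect_gte(cv$accuracy, 0.95)

  small <- fx$cohort[, c(1:4, 26:29, 51:54)]
  expect_error(crossValidate(small, cfg, nFolds = 5L), "fewer samples")
})

test_that("class-score gradients match closed forms and finite differences", {
  W <- matrix(c(0.5, -1, 2, 0.25, 1, -0.75), 3, 2)
  lin <- linearModel(W)
  g <- classScoreGradient(lin, c(1, 2, 3), "2")
  expect_equal(unname(g), W[, 2L])

  for (s in 1:3) {
    m <- randomReluMlp(12L, 10L, 3L, seed = s)
    x <- withr::with_seed(s, abs(rnorm(12L, 2, 1)))
    k <- 1L + (s %% 3L)
    g <- classScoreGradient(m, x, as.character(k))
    fd <- fdGradient(m, x, k)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
  }

  m <- randomReluMlp(10L, 8L, 2L, seed = 5L, dropoutP = 0.25)
  x <- withr::with_seed(5L, abs(rnorm(10L)))
  expect_identical(classScoreGradient(m, x, "1"),
                   classScoreGradient(m, x, "1"))
  g1 <- classScoreGradient(m, x, "1", dropoutEnabled = TRUE, seed = 1L)
  g1b <- classScoreGradient(m, x, "1", dropoutEnabled = TRUE, seed = 1L)
  g2 <- classScoreGradient(m, x, "1", dropoutEnabled = TRUE, seed = 2L)
  expect_identical(g1, g1b)
  expect_false(isTRUE(all.equal(g1, g2)))

  expect_error(classScoreGradient(m, x, "liver"), "unknown class")
})

test_that("CNN gradients agree with finite differences through the grid", {
  cfg <- modelConfig("CNN", nGenes = 60L, nClasses = 2L,
                     channels = c(3L, 4L, 4L, 4L, 2L),
                     kernelSizes = c(3L, 3L, 3L), gridSide = 24L,
                     dropoutP = 0, seed = 9L,
                     geneOrder = withr::with_seed(9L, sample.int(60L)))
  m <- buildModel(cfg)
  m@classLevels <- c("a", "b"); m@trained <- TRUE
  x <- withr::with_seed(10L, abs(rnorm(60L, 2, 1)))
  g <- classScoreGradient(m, x, "b")
  fd <- fdGradient(m, x, 2L)
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)
})
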