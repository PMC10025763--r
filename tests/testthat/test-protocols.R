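test_that("Spearman scoring matches a rank-then-Pearson oracle", {
  a <- c(1, 2, 3, 4)
  expect_equal(spearmanScore(a, a), 1)
  expect_equal(spearmanScore(a, rev(a)), -1)
  b <- c(1, 3, 2, 4)
  expect_equal(spearmanScore(a, b),
               stats::cor(rank(a), rank(b), method = "pearson"))
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(50))
    y <- withr::with_seed(s + 50L, rnorm(50))
    expect_equal(spearmanScore(x, y),
                 stats::cor(rank(x), rank(y), method = "pearson"))
  }
  expect_warning(out <- spearmanScore(rep(1, 5), a <- 1:5),
                 "rank variance")
  expect_true(is.na(out))
  expect_error(spearmanScore(1:2, 1:2), "length")
})

test_that("top-k overlap counts shared gene IDs with a stable tie-break", {
  g <- sprintf("g%03d", 1:200)
  a <- stats::setNames(200:1, g)
  expect_equal(topkOverlap(a, a, 100L), 1)

  # construct b sharing exactly 50 of a's top-100
  b <- stats::setNames(rep(0, 200), g)
  b[g[1:50]] <- 100    # shared half
  b[g[151:200]] <- 99  # half outside a's top-100
  expect_equal(topkOverlap(a, b, 100L), 0.5)

  disa <- stats::setNames(c(rep(1, 5), rep(0, 15)), sprintf("g%02d", 1:20))
  disb <- stats::setNames(c(rep(0, 15), rep(1, 5)), sprintf("g%02d", 1:20))
  expect_equal(topkOverlap(disa, disb, 5L), 0)

  tied <- stats::setNames(rep(1, 10), sprintf("g%02d", 10:1))
  expect_equal(topGenes(tied, 3L), c("g01", "g02", "g03"))
  expect_error(topkOverlap(disa, disb, 21L), "universe")
})

test_that("pairwise reports cover all replicate pairs", {
  g <- sprintf("g%03d", 1:150)
  reps5 <- lapply(1:5, function(i)
    stats::setNames(withr::with_seed(i, rnorm(150)), g))
  r5 <- pairwiseReport(reps5, k = 20L)
  expect_length(r5@pairwiseSpearman, choose(5, 2))
  expect_length(r5@pairwiseOverlap, 10L)

  r3 <- pairwiseReport(reps5[1:3], k = 20L)
  expect_length(r3@pairwiseSpearman, 3L)

  same <- pairwiseReport(reps5[c(1, 1, 1)], k = 20L)
  expect_equal(meanSpearman(same), 1)
  expect_equal(meanOverlap(same), 1)
  expect_error(pairwiseReport(reps5[1]), "replicates")
})

test_that("aggregation K-rule shrinks with aggregate size, floored at 4", {
  expect_equal(aggregationK(60L, 1L), 60L)
  expect_equal(aggregationK(60L, 30L), 4L)
  expect_equal(aggregationK(60L, 60L), 4L)
  expect_equal(aggregationK(12L, 3L), 4L)
  expect_equal(aggregationK(60L, 1L, rule = "literal"), 60L)
  expect_error(aggregationK(10L, 11L), "exceeds")
})

test_that("deterministic explainers degenerate every protocol to
           perfect reproducibility", {
  m <- randomReluMlp(40L, 12L, 2L, seed = 30L, dropoutP = 0.25)
  models <- list(m, m)   # identical models isolate protocol randomness
  x <- withr::with_seed(30L, abs(rnorm(40L, 2, 1)))

  sg <- smoothgradProtocol(x, models, "Saliency", "1", nGrid = c(1L, 5L),
                           noiseSd = 0, poolSize = 5L, k = 10L, seed = 1L)
  expect_true(all(sg$curve$meanSpearman == 1))
  expect_true(all(sg$curve$meanOverlap == 1))

  sr <- simpleRepeatProtocol(x, models, "DeepLift", "1",
                             nGrid = c(1L, 3L), poolSize = 5L, k = 10L,
                             dropoutEnabled = FALSE, seed = 1L)
  expect_true(all(sr$curve$meanSpearman == 1))
  expect_true(all(sr$curve$meanOverlap == 1))

  pool0 <- buildReferencePool(referenceSpec("zero", poolSize = 10L),
                              nGenes = 40L)
  rc <- referenceCountProtocol(x, models, "DeepLift", "1", pool0,
                               nGrid = c(1L, 4L), k = 10L, seed = 1L)
  expect_true(all(rc$curve$meanSpearman == 1))
  expect_true(all(rc$curve$meanOverlap == 1))

  ag <- aggregationProtocol(x, models, "Saliency", "1", nGrid = c(1L, 2L),
                            k = 10L, dropoutEnabled = FALSE, seed = 1L)
  expect_true(all(ag$curve$meanSpearman == 1))
  expect_true(all(ag$curve$meanOverlap == 1))
  # n = M: every aggregate uses all models; K floored at 4
  expect_equal(ag$reports[["2"]]@nReplicates, 4L)
})

test_that("zero-noise SmoothGrad equals the simple repeat protocol", {
  fx <- trainToyEnsemble(nModels = 2L, nGenes = 150L, nSamples = 25L,
                         epochs = 25L, seed = 41L)
  x <- t(exprValues(fx$split$test))[1L, ]
  tc <- tissueLabels(fx$split$test)[1L]
  sg <- smoothgradProtocol(x, fx$models, "Saliency", tc,
                           nGrid = c(1L, 3L), noiseSd = 0, poolSize = 5L,
                           k = 50L, dropoutEnabled = FALSE, seed = 3L)
  sr <- simpleRepeatProtocol(x, fx$models, "Saliency", tc,
                             nGrid = c(1L, 3L), poolSize = 5L, k = 50L,
                             dropoutEnabled = FALSE, seed = 3L)
  expect_equal(sg$curve$meanSpearman, sr$curve$meanSpearman)
  expect_equal(sg$curve$meanOverlap, sr$curve$meanOverlap)
})

test_that("averaging more repeats improves cross-model agreement", {
  fx <- trainToyEnsemble(nModels = 3L, nGenes = 200L, nSamples = 30L,
                         epochs = 30L, seed = 43L)
  x <- t(exprValues(fx$split$test))[1L, ]
  tc <- tissueLabels(fx$split$test)[1L]

  sr <- simpleRepeatProtocol(x, fx$models, "DeepLift", tc,
                             nGrid = c(1L, 10L, 40L), poolSize = 40L,
                             dropoutEnabled = TRUE, seed = 5L)
  expect_equal(sr$curve$n, c(1, 10, 40))
  expect_true(all(diff(sr$curve$meanSpearman) > -0.05))
  expect_gt(sr$curve$meanSpearman[3L], sr$curve$meanSpearman[1L])

  st <- geneStats(fx$cohort)
  pool <- buildReferencePool(referenceSpec("universal", poolSize = 80L,
                                           seed = 6L), stats = st)
  rc <- referenceCountProtocol(x, fx$models, "DeepLift", tc, pool,
                               nGrid = c(1L, 60L), dropoutEnabled = TRUE,
                               seed = 7L)
  expect_gte(rc$curve$meanSpearman[2L], rc$curve$meanSpearman[1L])

  ag <- aggregationProtocol(x, fx$models, "DeepLift", tc,
                            nGrid = c(1L, 3L), dropoutEnabled = TRUE,
                            seed = 8L)
  expect_gte(ag$curve$meanSpearman[2L], ag$curve$meanSpearman[1L])
  expect_error(aggregationProtocol(x, fx$models, "DeepLift", tc,
                                   nGrid = 5L), "exceed")
  expect_error(referenceCountProtocol(x, fx$models, "Saliency", tc, pool),
               "references")
})

test_that("cross-explainer matrix is symmetric with recoverable blocks", {
  g <- sprintf("g%03d", 1:100)
  setA <- g[1:20]; setB <- g[51:70]
  sets <- list(a1 = setA, a2 = setA, b1 = setB, b2 = setB)
  cem <- crossExplainerMatrix(sets)
  M <- cem$overlap
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 1))
  expect_equal(M["a1", "a2"], 1)
  expect_equal(M["b1", "b2"], 1)
  expect_equal(M["a1", "b1"], 0)
  # clustering places the two planted blocks contiguously
  ord <- names(sets)[cem$order]
  grp <- substr(ord, 1, 1)
  expect_true(all(grp == c("a", "a", "b", "b")) ||
                all(grp == c("b", "b", "a", "a")))
  expect_equal(crossExplainerMatrix(list(s1 = setA, s2 = setA,
                                         s3 = setA))$overlap,
               matrix(1, 3, 3, dimnames = list(c("s1", "s2", "s3"),
                                               c("s1", "s2", "s3"))))
  expect_error(crossExplainerMatrix(list(a = g[1:5], b = g[1:6])),
               "length")
})
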