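# two-hidden-unit worked ReLU net used for the pencil-and-paper DeepLIFT
# check: unit1 = relu(x1 + 2 x2 + 0.5), unit2 = relu(-x1 + x2 - 1),
# score1 = unit1 - 2 unit2
workedNet <- function() {
  m <- linearModel(diag(2))
  m@layers <- list(
    list(type = "dense", W = matrix(c(1, 2, -1, 1), 2, 2),
         b = c(0.5, -1)),
    list(type = "relu"),
    list(type = "dense", W = matrix(c(1, -2, 0, 0), 2, 2),
         b = c(0, 0)))
  m
}

test_that("explainers reduce to closed forms on a purely linear model", {
  W <- matrix(c(0.5, -1, 2, 0.25, 1, -0.75, 0.1, 0, 3), 3, 3)
  m <- linearModel(W)
  x <- c(1.5, 0.5, 2)

  expect_equal(unname(scores(saliency(m, x, "2"))), abs(W[, 2L]))
  expect_equal(unname(scores(saliency(m, x, "2", signed = TRUE))),
               W[, 2L])
  expect_equal(unname(scores(inputXGradient(m, x, "2"))), W[, 2L] * x)
  expect_equal(unname(scores(guidedBackprop(m, x, "2"))), W[, 2L])
  # with a zero baseline: IG (any step count) = DeepLift = InputXGradient
  for (ns in c(1L, 3L, 50L)) {
    expect_equal(unname(scores(integratedGradients(m, x, "2",
                                                   nSteps = ns))),
                 W[, 2L] * x, tolerance = 1e-12)
  }
  expect_equal(unname(scores(deepLift(m, x, "2"))), W[, 2L] * x)
  x0 <- c(0.2, 0.1, 0.4)
  expect_equal(unname(scores(deepLift(m, x, "2", reference = x0))),
               W[, 2L] * (x - x0))
  # zero input gives zero InputXGradient scores
  expect_equal(unname(scores(inputXGradient(m, numeric(3), "2"))),
               numeric(3))
  # constant model: zero weights for the target class
  expect_equal(unname(scores(saliency(m, x, "3"))), abs(W[, 3L]))
  pool <- withr::with_seed(2L, matrix(runif(12), 4, 3))
  expect_equal(unname(scores(deepLiftShap(m, x, "2", pool))),
               W[, 2L] * (x - colMeans(pool)), tolerance = 1e-12)
})

test_that("saliency and InputXGradient match the finite-difference oracle", {
  for (s in 1:5) {
    m <- randomReluMlp(10L, 8L, 3L, seed = 40L + s)
    x <- withr::with_seed(s, abs(rnorm(10L, 2, 1)))
    fd <- fdGradient(m, x, 2L)
    expect_lt(max(abs(scores(saliency(m, x, "2")) - abs(fd))) /
                max(abs(fd)), 1e-4)
    expect_lt(max(abs(scores(inputXGradient(m, x, "2")) - fd * x)) /
                max(abs(fd * x)), 1e-4)
  }
})

test_that("integrated gradients follow the midpoint Riemann rule", {
  m <- randomReluMlp(8L, 6L, 2L, seed = 50L)
  x <- withr::with_seed(50L, abs(rnorm(8L, 2, 1)))
  x0 <- withr::with_seed(51L, runif(8L, 0, 0.5))
  # independent 3-term midpoint quadrature from finite-difference gradients
  ig3 <- scores(integratedGradients(m, x, "1", reference = x0,
                                    nSteps = 3L))
  acc <- numeric(8L)
  for (k in 1:3) {
    pt <- x0 + (k - 0.5) / 3 * (x - x0)
    acc <- acc + fdGradient(m, pt, 1L)
  }
  oracle <- (x - x0) * acc / 3
  expect_lt(max(abs(ig3 - oracle)), 1e-6 * max(abs(oracle)))
  expect_error(integratedGradients(m, x, "1", nSteps = 0L), "nSteps")
  expect_error(integratedGradients(m, x, "1", reference = numeric(3)),
               "length")
})

test_that("IG completeness holds exactly on kink-free paths and converges
           as O(1/n) across kinks", {
  # zero baseline, freshly initialized net: the activation pattern is
  # constant along the path, midpoint quadrature is exact
  m <- randomReluMlp(10L, 8L, 2L, seed = 60L)
  x <- withr::with_seed(60L, abs(rnorm(10L, 2, 1)))
  dF <- modelScore(m, x, 1L) - modelScore(m, numeric(10L), 1L)
  ig <- scores(integratedGradients(m, x, "1", nSteps = 512L))
  expect_lt(abs(sum(ig) - dF), 1e-4 * abs(dF))

  # shifted biases put ReLU crossings on the path: error is finite and
  # shrinks with the step count
  m@layers[[1L]]$b <- withr::with_seed(61L, rnorm(8L, 0, 0.5))
  m@layers[[2L]]$rm <- withr::with_seed(62L, rnorm(8L, 0, 0.5))
  x0 <- withr::with_seed(63L, runif(10L))
  dF <- modelScore(m, x, 1L) - modelScore(m, x0, 1L)
  err <- vapply(c(64L, 1024L), function(ns)
    abs(sum(scores(integratedGradients(m, x, "1", reference = x0,
                                       nSteps = ns))) - dF),
    numeric(1))
  expect_lt(err[1L], 0.05 * abs(dF))
  expect_lte(err[2L], err[1L] + 1e-12)
})

test_that("DeepLIFT matches the hand-worked rescale calculation", {
  m <- workedNet()
  # x=(1,1), x0=(0,0): deltas 3.5-0.5 and 0; unit2 falls back to its local
  # gradient (inactive); multipliers to inputs are (1, 2); scores (1, 2)
  dl <- scores(deepLift(m, c(1, 1), "1"))
  expect_equal(unname(dl), c(1, 2))
  dF <- modelScore(m, c(1, 1), 1L) - modelScore(m, c(0, 0), 1L)
  expect_equal(sum(dl), dF)
})

test_that("DeepLIFT summation-to-delta holds on random ReLU nets", {
  for (s in 1:25) {
    nin <- 4L + (s %% 8L)
    m <- randomReluMlp(nin, 4L + (s %% 6L), 2L, seed = 70L + s)
    m@layers[[1L]]$b <- withr::with_seed(s, rnorm(length(
      m@layers[[1L]]$b), 0, 0.5))
    x <- withr::with_seed(s + 100L, abs(rnorm(nin, 2, 1)))
    x0 <- withr::with_seed(s + 200L, runif(nin))
    dl <- scores(deepLift(m, x, "1", reference = x0))
    dF <- modelScore(m, x, 1L) - modelScore(m, x0, 1L)
    expect_lt(abs(sum(dl) - dF), 1e-5 * max(abs(dF), 1e-8))
  }
})

test_that("DeepLiftShap averages DeepLIFT over drawn baselines", {
  m <- randomReluMlp(8L, 6L, 2L, seed = 80L)
  x <- withr::with_seed(80L, abs(rnorm(8L, 2, 1)))
  ref <- withr::with_seed(81L, runif(8L))
  one <- matrix(ref, 1L)
  expect_equal(scores(deepLiftShap(m, x, "1", one)),
               scores(deepLift(m, x, "1", reference = ref)))

  pool <- withr::with_seed(82L, matrix(runif(40L), 5L))
  dls <- scores(deepLiftShap(m, x, "1", pool))
  delta <- mean(apply(pool, 1L, function(r)
    modelScore(m, x, 1L) - modelScore(m, r, 1L)))
  expect_lt(abs(sum(dls) - delta), 1e-5 * abs(delta))
  expect_error(deepLiftShap(m, x, "1", numeric(0)), "non-empty")
})

test_that("guided backprop masks negative upstream signal at ReLUs", {
  # linear model: no ReLU, guided equals the plain gradient (covered in
  # the linear block); all-positive weights and inputs: also equal
  m <- linearModel(diag(2))
  m@layers <- list(
    list(type = "dense", W = matrix(abs(c(1, 2, 0.5, 1)), 2, 2),
         b = c(0.1, 0.2)),
    list(type = "relu"),
    list(type = "dense", W = matrix(abs(c(0.7, 0.3, 0.2, 0.6)), 2, 2),
         b = c(0, 0)))
  x <- c(1, 2)
  expect_equal(scores(guidedBackprop(m, x, "1")),
               classScoreGradient(m, x, "1"))

  # single active ReLU unit with a negative upstream gradient: guided
  # attribution is zero while the plain gradient is not
  m2 <- linearModel(matrix(1, 1, 2))
  m2@layers <- list(
    list(type = "dense", W = matrix(1, 1, 1), b = 0),
    list(type = "relu"),
    list(type = "dense", W = matrix(c(-1, 0), 1, 2), b = c(0, 0)))
  expect_equal(unname(scores(guidedBackprop(m2, 2, "1"))), 0)
  expect_equal(unname(classScoreGradient(m2, 2, "1")), -1)

  # on chain networks (one unit per hidden layer) the guided mask is a
  # 0/1 factor on the gradient, so signs agree wherever both are nonzero
  for (s in 1:5) {
    m3 <- linearModel(matrix(1, 6, 2))
    wts <- withr::with_seed(s, rnorm(9))
    m3@layers <- list(
      list(type = "dense", W = matrix(wts[1:6], 6, 1), b = wts[7]),
      list(type = "relu"),
      list(type = "dense", W = matrix(c(wts[8], 0), 1, 2), b = c(0, 0)),
      list(type = "relu"),
      list(type = "dense", W = matrix(c(wts[9], 0), 2, 2), b = c(0, 0)))
    x <- withr::with_seed(s + 20L, rnorm(6))
    gb <- scores(guidedBackprop(m3, x, "1"))
    g <- classScoreGradient(m3, x, "1")
    both <- gb != 0 & g != 0
    expect_true(all(sign(gb[both]) == sign(g[both])))
  }
})

test_that("guided Grad-CAM matches the single-channel manual oracle", {
  # togrid(2x2) -> 1x1 conv (weight w) -> ReLU -> GAP -> dense: for a
  # positive input every stage is linear, so the map is
  # relu(mean(G) * A) with A = w x_cell and G = v1/4, and the guided
  # gradient per gene is v1 w / 4
  w <- 0.8; v1 <- 1.2
  m <- linearModel(diag(4))
  m@layers <- list(
    list(type = "togrid", side = 2L, geneOrder = 1:4,
         colperm = transXplain:::.rowMajorColperm(2L),
         invcolperm = order(transXplain:::.rowMajorColperm(2L))),
    list(type = "conv", kh = 1L, kw = 1L, cin = 1L, cout = 1L,
         W = array(w, c(1, 1, 1, 1)), b = 0),
    list(type = "relu"),
    list(type = "gap"),
    list(type = "dense", W = matrix(c(v1, 0), 1, 2), b = c(0, 0)))
  m@arch <- "CNN"
  m@config$camLayer <- 3L
  m@config$gridSide <- 2L
  m@config$geneOrder <- 1:4
  m@config$nClasses <- 2L
  x <- c(1, 2, 3, 4)
  got <- scores(guidedGradCam(m, x, "1"))
  manual <- pmax((v1 / 4) * (w * x), 0) * (v1 * w / 4)
  expect_equal(unname(got), manual)

  # all-zero feature-map gradients (target with zero output weights)
  expect_equal(unname(scores(guidedGradCam(m, x, "2"))), numeric(4))
  expect_equal(unname(scores(guidedGradCam(m, x, "2", "gradcam++"))),
               numeric(4))
})

test_that("Grad-CAM output covers all genes and rejects MLP models", {
  cfg <- modelConfig("CNN", nGenes = 50L, nClasses = 2L,
                     channels = c(3L, 4L, 4L, 4L, 2L),
                     kernelSizes = c(3L, 3L, 3L), gridSide = 24L,
                     seed = 3L)
  m <- buildModel(cfg)
  m@classLevels <- c("a", "b"); m@trained <- TRUE
  x <- withr::with_seed(4L, abs(rnorm(50L, 2, 1)))
  for (v in c("gradcam", "gradcam++")) {
    s <- scores(guidedGradCam(m, x, "a", v))
    expect_length(s, 50L)
    expect_true(all(is.finite(s)))
  }
  mlp <- randomReluMlp(10L, 4L, 2L, seed = 1L)
  expect_error(guidedGradCam(mlp, rnorm(10), "1"), "CNN")
  expect_error(explain(mlp, rnorm(10), "GuidedGradCam++", "1"), "CNN")
})

test_that("explain() dispatches, and dropout seeding is the only
           source of variability", {
  m <- randomReluMlp(10L, 8L, 2L, seed = 95L, dropoutP = 0.25)
  x <- withr::with_seed(95L, abs(rnorm(10L, 2, 1)))
  expect_equal(scores(explain(m, x, "Saliency", "1")),
               scores(saliency(m, x, "1")))
  expect_equal(scores(explain(m, x, "DeepLift", "1")),
               scores(deepLift(m, x, "1")))
  expect_error(explain(m, x, "NotAMethod", "1"), "unknown explainer")

  a1 <- scores(explain(m, x, "DeepLift", "1", dropoutEnabled = TRUE,
                       seed = 7L))
  a2 <- scores(explain(m, x, "DeepLift", "1", dropoutEnabled = TRUE,
                       seed = 7L))
  a3 <- scores(explain(m, x, "DeepLift", "1", dropoutEnabled = TRUE,
                       seed = 8L))
  expect_identical(a1, a2)
  expect_false(isTRUE(all.equal(a1, a3)))
  expect_identical(scores(explain(m, x, "IntegratedGradients", "1")),
                   scores(explain(m, x, "IntegratedGradients", "1")))
})

test_that("MLP attributions are invariant to gene-order permutation", {
  m <- randomReluMlp(8L, 6L, 2L, seed = 97L)
  perm <- withr::with_seed(97L, sample.int(8L))
  m2 <- m
  m2@layers[[1L]]$W <- m@layers[[1L]]$W[perm, , drop = FALSE]
  x <- withr::with_seed(98L, abs(rnorm(8L, 2, 1)))
  y <- x[order(perm)]   # so that y[perm] == x
  for (ex in c("Saliency", "InputXGradient", "GuidedBackprop",
               "IntegratedGradients", "DeepLift")) {
    a <- unname(scores(explain(m, y, ex, "1")))
    b <- unname(scores(explain(m2, x, ex, "1")))
    expect_equal(b, a[perm], tolerance = 1e-12)
  }
})
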