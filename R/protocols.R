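#' Spearman rank correlation between two score vectors
#'
#' Rank correlation with average ranks for ties. When either vector has
#' zero rank variance the coefficient is undefined and `NA` is returned
#' with a warning.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return Correlation coefficient in \[-1, 1\], or `NA`.
#' @export
spearmanScore <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L)
    .stopf("'a' and 'b' must have equal length >= 3")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    .stopf("score vectors must be finite")
  ra <- rank(a)
  rb <- rank(b)
  if (sd(ra) == 0 || sd(rb) == 0) {
    warning("zero rank variance: Spearman coefficient undefined",
            call. = FALSE)
    return(NA_real_)
  }
  # perfectly concordant/discordant rankings are exact by construction;
  # bypass the floating-point summation inside cor()
  if (identical(ra, rb)) return(1)
  if (identical(ra, length(rb) + 1 - rb)) return(-1)
  cor(ra, rb, method = "pearson")
}

#' Top-k overlap between two rankings
#'
#' Fraction of shared gene IDs among the k highest-scoring genes of the two
#' vectors. Ranking is by descending score with a deterministic gene-ID
#' tie-break.
#'
#' @param a,b named numeric score vectors over the same gene universe.
#' @param k top-k cutoff (default 100).
#' @return Overlap fraction in \[0, 1\].
#' @export
topkOverlap <- function(a, b, k = 100L) {
  if (k > length(a)) .stopf("k (%d) exceeds the gene universe (%d)", k,
                            length(a))
  length(intersect(topGenes(a, k), topGenes(b, k))) / k
}

#' @describeIn topkOverlap ids of the k top-ranked genes of one vector.
#' @param x named numeric score vector.
#' @export
topGenes <- function(x, k = 100L) {
  ids <- names(x) %||% as.character(seq_along(x))
  ids[order(-x, ids)][seq_len(k)]
}

.newReport <- function(vectors, k, axis, params = list()) {
  n <- length(vectors)
  if (n < 2L) .stopf("a replicate set needs >= 2 replicates")
  lens <- lengths(vectors)
  if (length(unique(lens)) != 1L)
    .stopf("replicates must share one gene universe")
  pairs <- combn(n, 2L)
  sp <- ov <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- vectors[[pairs[1L, j]]]
    b <- vectors[[pairs[2L, j]]]
    sp[j] <- spearmanScore(a, b)
    ov[j] <- topkOverlap(a, b, k)
  }
  new("ReproducibilityReport", pairwiseSpearman = sp, pairwiseOverlap = ov,
      k = as.integer(k), nReplicates = as.integer(n), axis = axis,
      params = params)
}

#' Pairwise reproducibility report over a replicate set
#'
#' Evaluates all `choose(n, 2)` unordered replicate pairs by Spearman
#' correlation and top-k overlap; 5 replicates yield 10 pairs.
#'
#' @param replicates list of named numeric score vectors (or a list of
#'   [Attribution-class] objects) over one gene universe.
#' @param k top-k cutoff (default 100).
#' @param axis label of the axis of variability.
#' @return A [ReproducibilityReport-class].
#' @export
pairwiseReport <- function(replicates, k = 100L, axis = "replicates") {
  vecs <- lapply(replicates, function(r)
    if (is(r, "Attribution")) scores(r) else r)
  .newReport(vecs, k, axis)
}

.curveRow <- function(n, rep_) {
  data.frame(n = n, meanSpearman = meanSpearman(rep_),
             sdSpearman = sd(rep_@pairwiseSpearman),
             meanOverlap = meanOverlap(rep_),
             sdOverlap = sd(rep_@pairwiseOverlap),
             nPairs = length(rep_@pairwiseSpearman))
}

.protocolResult <- function(rows, reports, protocol) {
  structure(list(curve = do.call(rbind, rows), reports = reports,
                 protocol = protocol), class = "ProtocolCurve")
}

#' @export
print.ProtocolCurve <- function(x, ...) {
  cat(sprintf("ProtocolCurve [%s]\n", x$protocol))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

# average selected precomputed replicate vectors (rows of `mat`)
.avgRows <- function(mat, idx) {
  if (length(idx) == 1L) mat[idx, ] else colMeans(mat[idx, , drop = FALSE])
}

.attrScores <- function(model, sample, explainerId, targetClass, ...,
                        seed) {
  scores(explain(model, sample, explainerId, targetClass, ..., seed = seed))
}

#' Noise-averaged (SmoothGrad-style) optimization protocol
#'
#' For each model, generates a pool of `poolSize` pseudo-samples by adding
#' `N(0, noiseSd)` noise to each gene of the sample (on the log2 scale,
#' unclipped by default), attributes each pseudo-sample, and for each `n`
#' in `nGrid` averages `n` attribution vectors drawn without replacement
#' from the pool. The `n`-averaged vectors from the different models form a
#' replicate set whose pairwise reproducibility is reported per `n`.
#'
#' @param sample gene-expression vector.
#' @param models list of >= 2 trained [TissueClassifier-class] objects.
#' @param explainerId explainer identifier (see [explain()]).
#' @param targetClass class whose score is attributed.
#' @param nGrid numbers of pseudo-samples to average (all <= `poolSize`).
#' @param noiseSd standard deviation of the added noise (default 1).
#' @param poolSize pseudo-sample pool size per model (default 50).
#' @param k top-k cutoff for overlaps.
#' @param clip clip noisy pseudo-samples at 0 (default FALSE).
#' @param dropoutEnabled enable dropout during attribution (default FALSE;
#'   noise is the intended source of variability here).
#' @param seed integer seed.
#' @param ... further arguments passed to [explain()] (references etc.).
#' @return A `ProtocolCurve`: `curve` data.frame (n, meanSpearman,
#'   sdSpearman, meanOverlap, sdOverlap, nPairs) plus the per-n
#'   [ReproducibilityReport-class] objects.
#' @export
smoothgradProtocol <- function(sample, models, explainerId, targetClass,
                               nGrid = c(1L, 5L, 10L, 25L, 50L),
                               noiseSd = 1, poolSize = 50L, k = 100L,
                               clip = FALSE, dropoutEnabled = FALSE,
                               seed = 1L, ...) {
  if (length(models) < 2L) .stopf("need >= 2 models")
  if (any(nGrid > poolSize))
    .stopf("nGrid values must not exceed poolSize (%d)", poolSize)
  perModel <- lapply(seq_along(models), function(j) {
    mdl <- models[[j]]
    x <- .inputMatrix(mdl, sample)[1L, ]
    pool <- matrix(0, poolSize, length(x))
    for (i in seq_len(poolSize)) {
      xi <- if (noiseSd > 0)
        x + .withSeed(deriveSeed(seed, 810, j, i),
                      rnorm(length(x), 0, noiseSd))
      else x
      if (clip) xi <- pmax(xi, 0)
      pool[i, ] <- .attrScores(mdl, xi, explainerId, targetClass, ...,
                               dropoutEnabled = dropoutEnabled,
                               seed = deriveSeed(seed, 811, j, i))
    }
    colnames(pool) <- mdl@geneIds
    pool
  })
  .gridReports(perModel, nGrid, k, seed, 812, "smoothgrad")
}

#' Simple-repeat optimization protocol
#'
#' Re-runs the explainer on the unmodified sample `poolSize` times per
#' model; with dropout enabled each repeat draws a fresh dropout mask,
#' which is the source of variability. For each `n` in `nGrid`, `n`
#' attribution vectors drawn without replacement are averaged, and the
#' averaged vectors from different models are compared pairwise.
#'
#' @inheritParams smoothgradProtocol
#' @param poolSize number of repeats per model (default 50).
#' @export
simpleRepeatProtocol <- function(sample, models, explainerId, targetClass,
                                 nGrid = c(1L, 5L, 10L, 25L, 50L),
                                 poolSize = 50L, k = 100L,
                                 dropoutEnabled = TRUE, seed = 1L, ...) {
  if (length(models) < 2L) .stopf("need >= 2 models")
  if (any(nGrid > poolSize))
    .stopf("nGrid values must not exceed poolSize (%d)", poolSize)
  perModel <- lapply(seq_along(models), function(j) {
    mdl <- models[[j]]
    x <- .inputMatrix(mdl, sample)[1L, ]
    pool <- matrix(0, poolSize, length(x))
    for (i in seq_len(poolSize))
      pool[i, ] <- .attrScores(mdl, x, explainerId, targetClass, ...,
                               dropoutEnabled = dropoutEnabled,
                               seed = deriveSeed(seed, 820, j, i))
    colnames(pool) <- mdl@geneIds
    pool
  })
  .gridReports(perModel, nGrid, k, seed, 821, "simple_repeat")
}

# shared tail of the pool-averaging protocols: draw n rows per model,
# average, report across models, per n
.gridReports <- function(perModel, nGrid, k, seed, tag, protocol) {
  reports <- list()
  rows <- list()
  for (n in nGrid) {
    reps <- lapply(seq_along(perModel), function(j) {
      pick <- .withSeed(deriveSeed(seed, tag, j, n),
                        sample.int(nrow(perModel[[j]]), n))
      stats::setNames(.avgRows(perModel[[j]], pick),
                      colnames(perModel[[j]]))
    })
    rep_ <- .newReport(reps, k, "inter_model", list(n = n))
    reports[[as.character(n)]] <- rep_
    rows[[as.character(n)]] <- .curveRow(n, rep_)
  }
  .protocolResult(rows, reports, protocol)
}

#' Reference-count optimization protocol
#'
#' For explainers that require a baseline (DeepLift, DeepLiftShap,
#' IntegratedGradients), averages the attribution over `n` references drawn
#' without replacement from a reference pool, for each `n` in `nGrid`, and
#' reports cross-model reproducibility per `n`. Per-reference attributions
#' are cached per model, so each pool row is attributed at most once.
#'
#' @inheritParams smoothgradProtocol
#' @param referencePool matrix of baselines from [buildReferencePool()].
#' @param nGrid reference counts (full-scale protocols sweep 1..100 from
#'   a pool of 2000).
#' @param nSteps IntegratedGradients quadrature steps.
#' @export
referenceCountProtocol <- function(sample, models, explainerId,
                                   targetClass, referencePool,
                                   nGrid = c(1L, 5L, 20L, 60L, 100L),
                                   k = 100L, nSteps = 50L,
                                   dropoutEnabled = FALSE, seed = 1L) {
  if (!explainerId %in% c("DeepLift", "DeepLiftShap",
                          "IntegratedGradients"))
    .stopf("explainer '%s' does not use references", explainerId)
  if (length(models) < 2L) .stopf("need >= 2 models")
  if (any(nGrid > nrow(referencePool)))
    .stopf("nGrid values must not exceed the pool size (%d)",
           nrow(referencePool))
  caches <- lapply(models, function(m) new.env(parent = emptyenv()))
  attrForRef <- function(j, i) {
    key <- as.character(i)
    env <- caches[[j]]
    if (is.null(env[[key]])) {
      mdl <- models[[j]]
      x <- .inputMatrix(mdl, sample)[1L, ]
      masks <- .explainMasks(mdl, dropoutEnabled,
                             deriveSeed(seed, 830, j, i))
      kIdx <- .targetIndex(mdl, targetClass)
      env[[key]] <- if (explainerId == "IntegratedGradients")
        .igCore(mdl, x, referencePool[i, ], kIdx, nSteps, masks)
      else .deepliftCore(mdl, x, referencePool[i, ], kIdx, masks)
    }
    env[[key]]
  }
  reports <- list(); rows <- list()
  for (n in nGrid) {
    reps <- lapply(seq_along(models), function(j) {
      pick <- .withSeed(deriveSeed(seed, 831, j, n),
                        sample.int(nrow(referencePool), n))
      acc <- Reduce(`+`, lapply(pick, function(i) attrForRef(j, i)))
      stats::setNames(acc / n, models[[j]]@geneIds)
    })
    rep_ <- .newReport(reps, k, "inter_model", list(n = n))
    reports[[as.character(n)]] <- rep_
    rows[[as.character(n)]] <- .curveRow(n, rep_)
  }
  .protocolResult(rows, reports, "reference_count")
}

#' Number of aggregated replicates for the model-aggregation protocol
#'
#' With `rule = "ratio"` (default), `K = max(ceiling(M / n), 4)`: the
#' number of aggregated replicates shrinks as each aggregate consumes more
#' models, floored at 4 so a pairwise comparison always exists. `M = 60`
#' gives `K = 60` at `n = 1` and `K = 4` at `n = 30`. `rule = "literal"`
#' uses `K = max(M * n, 4)`.
#'
#' @param M number of available models.
#' @param n aggregation size.
#' @param rule "ratio" or "literal".
#' @return Integer `K`.
#' @export
aggregationK <- function(M, n, rule = c("ratio", "literal")) {
  rule <- match.arg(rule)
  if (n > M) .stopf("aggregation size n (%d) exceeds models M (%d)", n, M)
  as.integer(switch(rule,
    ratio = max(ceiling(M / n), 4L),
    literal = max(M * n, 4L)))
}

#' Model-aggregation optimization protocol
#'
#' Each of the `M` models is attributed once; for each aggregation size `n`
#' in `nGrid`, `K = ` [aggregationK()] aggregated replicates are formed
#' (each the mean over `n` models sampled without replacement) and all
#' `choose(K, 2)` pairs are scored.
#'
#' @inheritParams smoothgradProtocol
#' @param nGrid aggregation sizes (all <= `length(models)`).
#' @param kRule K-rule variant, see [aggregationK()].
#' @export
aggregationProtocol <- function(sample, models, explainerId, targetClass,
                                nGrid = c(1L, 2L, 5L, 10L), k = 100L,
                                kRule = c("ratio", "literal"),
                                dropoutEnabled = TRUE, seed = 1L, ...) {
  kRule <- match.arg(kRule)
  M <- length(models)
  if (M < 2L) .stopf("need >= 2 models")
  if (any(nGrid > M)) .stopf("nGrid values must not exceed M (%d)", M)
  base <- t(vapply(seq_len(M), function(j)
    .attrScores(models[[j]], sample, explainerId, targetClass, ...,
                dropoutEnabled = dropoutEnabled,
                seed = deriveSeed(seed, 840, j)),
    numeric(models[[1L]]@config$nGenes)))
  colnames(base) <- models[[1L]]@geneIds
  reports <- list(); rows <- list()
  for (n in nGrid) {
    K <- aggregationK(M, n, kRule)
    reps <- lapply(seq_len(K), function(r) {
      pick <- .withSeed(deriveSeed(seed, 841, n, r), sample.int(M, n))
      stats::setNames(.avgRows(base, pick), colnames(base))
    })
    rep_ <- .newReport(reps, k, "aggregated", list(n = n, K = K))
    reports[[as.character(n)]] <- rep_
    rows[[as.character(n)]] <- .curveRow(n, rep_)
  }
  .protocolResult(rows, reports, "aggregation")
}

#' Cross-explainer consistency matrix
#'
#' Pairwise top-k overlap between top-gene sets from different
#' (explainer, architecture, aggregation) configurations, with an
#' average-linkage hierarchical ordering for block display.
#'
#' @param sets named list of top-k gene-ID character vectors over one gene
#'   universe (all the same length).
#' @return `list(overlap = symmetric matrix with unit diagonal,
#'   order = display ordering, hclust = the clustering)`.
#' @export
crossExplainerMatrix <- function(sets) {
  if (length(sets) < 2L) .stopf("need >= 2 gene sets")
  lens <- lengths(sets)
  if (length(unique(lens)) != 1L)
    .stopf("all top-k sets must have the same length")
  k <- lens[[1L]]
  m <- length(sets)
  M <- diag(1, m)
  dimnames(M) <- list(names(sets), names(sets))
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m)
    M[i, j] <- M[j, i] <-
      length(intersect(sets[[i]], sets[[j]])) / k
  hc <- hclust(as.dist(1 - M), method = "average")
  list(overlap = M, order = hc$order, hclust = hc)
}
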