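#' @name explainers
#' @title Attribution explainers
#'
#' @description Eight backpropagation-based attribution methods producing
#' per-gene contribution scores for one sample and one target class:
#' Saliency, InputXGradient, GuidedBackprop, IntegratedGradients, DeepLift
#' (rescale rule), DeepLiftShap, GuidedGradCam and GuidedGradCam++ (the two
#' Grad-CAM variants apply to CNN models only). All methods differentiate
#' the pre-softmax score of the target class.
#'
#' With `dropoutEnabled`, each call draws one fresh dropout mask from
#' `seed`, applies it in the forward pass and respects it in the backward
#' pass; this is the source of intra-model attribution variability
#' exploited by the repeat protocols. With it disabled, calls are
#' deterministic.
NULL

.explainerIds <- c("Saliency", "InputXGradient", "GuidedBackprop",
                   "IntegratedGradients", "DeepLift", "DeepLiftShap",
                   "GuidedGradCam", "GuidedGradCam++")

.wrapAttribution <- function(scores, model, explainerId, targetClass,
                             sampleId = "sample", reference = "none",
                             replicateId = "r1") {
  new("Attribution", scores = stats::setNames(as.vector(scores),
                                              model@geneIds),
      sampleId = sampleId, explainerId = explainerId,
      modelId = sprintf("%s_seed%d", model@arch, model@config$seed),
      replicateId = replicateId, targetClass = targetClass,
      reference = reference)
}

.explainMasks <- function(model, dropoutEnabled, seed) {
  if (isTRUE(dropoutEnabled)) .drawDropoutMasks(model, seed) else NULL
}

# ---- numeric cores (vectors in, vectors out) ------------------------------

.saliencyCore <- function(model, x, targetIdx, masks, signed = FALSE) {
  g <- .gradBatch(model, matrix(x, 1L), targetIdx, masks = masks)
  if (signed) as.vector(g) else abs(as.vector(g))
}

.inputXGradientCore <- function(model, x, targetIdx, masks) {
  g <- .gradBatch(model, matrix(x, 1L), targetIdx, masks = masks)
  as.vector(g) * x
}

.guidedBackpropCore <- function(model, x, targetIdx, masks) {
  as.vector(.gradBatch(model, matrix(x, 1L), targetIdx, mode = "guided",
                       masks = masks))
}

.igCore <- function(model, x, x0, targetIdx, nSteps, masks) {
  if (nSteps < 1L) .stopf("'nSteps' must be >= 1")
  if (length(x0) != length(x))
    .stopf("reference length %d does not match sample length %d",
           length(x0), length(x))
  alphas <- (seq_len(nSteps) - 0.5) / nSteps
  pts <- outer(alphas, x - x0, `*`)
  pts <- sweep(pts, 2, x0, `+`)
  g <- .gradBatch(model, pts, targetIdx, masks = masks)
  (x - x0) * colMeans(g)
}

.deepliftCore <- function(model, x, x0, targetIdx, masks) {
  if (length(x0) != length(x))
    .stopf("reference length %d does not match sample length %d",
           length(x0), length(x))
  fwX <- .modelForward(model, matrix(x, 1L), masks = masks,
                       keepCache = TRUE)
  fwR <- .modelForward(model, matrix(x0, 1L), masks = masks,
                       keepCache = TRUE)
  dscores <- matrix(0, 1L, model@config$nClasses)
  dscores[, targetIdx] <- 1
  m <- .deepliftMultipliers(model, fwX$caches, fwR$caches, dscores)
  as.vector(m) * (x - x0)
}

.avgOverReferences <- function(model, x, refs, targetIdx, core, ...) {
  acc <- numeric(length(x))
  for (i in seq_len(nrow(refs)))
    acc <- acc + core(model, x, refs[i, ], targetIdx, ...)
  acc / nrow(refs)
}

.bilinearUpsample <- function(m, S) {
  h <- nrow(m); w <- ncol(m)
  mapIdx <- function(n, S) {
    u <- (seq_len(S) - 0.5) * n / S + 0.5
    i0 <- pmin(pmax(floor(u), 1L), n)
    i1 <- pmin(i0 + 1L, n)
    fr <- pmin(pmax(u - i0, 0), 1)
    list(i0 = i0, i1 = i1, fr = fr)
  }
  r <- mapIdx(h, S); cc <- mapIdx(w, S)
  top <- m[r$i0, cc$i0, drop = FALSE] * (1 - cc$fr[col(matrix(0, S, S))]) +
         m[r$i0, cc$i1, drop = FALSE] * cc$fr[col(matrix(0, S, S))]
  bot <- m[r$i1, cc$i0, drop = FALSE] * (1 - cc$fr[col(matrix(0, S, S))]) +
         m[r$i1, cc$i1, drop = FALSE] * cc$fr[col(matrix(0, S, S))]
  fr <- r$fr[row(matrix(0, S, S))]
  top * (1 - fr) + bot * fr
}

.gradcamCore <- function(model, x, targetIdx, variant, masks) {
  if (model@arch != "CNN")
    .stopf("GuidedGradCam(++) applies to CNN models only")
  cam <- model@config$camLayer
  fw <- .modelForward(model, matrix(x, 1L), masks = masks,
                      keepCache = TRUE)
  A <- pmax(fw$caches[[cam]]$x, 0)      # feature maps after the final ReLU
  dscores <- matrix(0, 1L, model@config$nClasses)
  dscores[, targetIdx] <- 1
  G <- .modelBackward(model, fw$caches, dscores, stopAfter = cam)$grad
  d <- dim(A)
  h <- d[2L]; w <- d[3L]; C <- d[4L]
  camMap <- matrix(0, h, w)
  for (ch in seq_len(C)) {
    a <- matrix(A[1L, , , ch], h, w)
    g <- matrix(G[1L, , , ch], h, w)
    wc <- if (variant == "gradcam") {
      mean(g)
    } else {
      denom <- 2 * g^2 + sum(a * g^3)
      alpha <- ifelse(abs(denom) > 1e-12, g^2 / denom, 0)
      sum(alpha * pmax(g, 0))
    }
    camMap <- camMap + wc * a
  }
  camMap <- pmax(camMap, 0)
  S <- model@config$gridSide
  camUp <- .bilinearUpsample(camMap, S)
  gb <- .guidedBackpropCore(model, x, targetIdx, masks)
  cfg <- model@config
  class(cfg) <- "ModelConfig"
  gbGrid <- reshapeToGrid(gb, cfg)
  flattenFromGrid(camUp * gbGrid, cfg)
}

# ---- exported explainer functions -----------------------------------------

#' @rdname explainers
#' @param model a trained [TissueClassifier-class].
#' @param sample gene-expression vector (log2(TPM+1)).
#' @param targetClass class whose pre-softmax score is attributed.
#' @param signed return signed gradients instead of absolute values
#'   (Saliency only; the absolute value is the conventional default).
#' @param dropoutEnabled draw and apply one dropout mask (see Description).
#' @param seed seed for the dropout mask.
#' @export
saliency <- function(model, sample, targetClass, signed = FALSE,
                     dropoutEnabled = FALSE, seed = 1L) {
  masks <- .explainMasks(model, dropoutEnabled, seed)
  s <- .saliencyCore(model, .inputMatrix(model, sample)[1L, ],
                     .targetIndex(model, targetClass), masks, signed)
  .wrapAttribution(s, model, "Saliency", targetClass)
}

#' @rdname explainers
#' @export
inputXGradient <- function(model, sample, targetClass,
                           dropoutEnabled = FALSE, seed = 1L) {
  masks <- .explainMasks(model, dropoutEnabled, seed)
  s <- .inputXGradientCore(model, .inputMatrix(model, sample)[1L, ],
                           .targetIndex(model, targetClass), masks)
  .wrapAttribution(s, model, "InputXGradient", targetClass)
}

#' @rdname explainers
#' @export
guidedBackprop <- function(model, sample, targetClass,
                           dropoutEnabled = FALSE, seed = 1L) {
  masks <- .explainMasks(model, dropoutEnabled, seed)
  s <- .guidedBackpropCore(model, .inputMatrix(model, sample)[1L, ],
                           .targetIndex(model, targetClass), masks)
  .wrapAttribution(s, model, "GuidedBackprop", targetClass)
}

#' @rdname explainers
#' @param reference baseline vector (same length as `sample`); defaults to
#'   the all-zero reference.
#' @param nSteps number of midpoint Riemann steps for the path integral
#'   (default 50); attributions satisfy the completeness axiom in the
#'   large-`nSteps` limit.
#' @export
integratedGradients <- function(model, sample, targetClass,
                                reference = NULL, nSteps = 50L,
                                dropoutEnabled = FALSE, seed = 1L) {
  x <- .inputMatrix(model, sample)[1L, ]
  if (is.null(reference)) reference <- numeric(length(x))
  masks <- .explainMasks(model, dropoutEnabled, seed)
  s <- .igCore(model, x, reference, .targetIndex(model, targetClass),
               as.integer(nSteps), masks)
  .wrapAttribution(s, model, "IntegratedGradients", targetClass,
                   reference = "vector")
}

#' @rdname explainers
#' @export
deepLift <- function(model, sample, targetClass, reference = NULL,
                     dropoutEnabled = FALSE, seed = 1L) {
  x <- .inputMatrix(model, sample)[1L, ]
  if (is.null(reference)) reference <- numeric(length(x))
  masks <- .explainMasks(model, dropoutEnabled, seed)
  s <- .deepliftCore(model, x, reference,
                     .targetIndex(model, targetClass), masks)
  .wrapAttribution(s, model, "DeepLift", targetClass,
                   reference = "vector")
}

#' @rdname explainers
#' @param referencePool matrix of candidate baselines, one per row (see
#'   [buildReferencePool()]).
#' @param nReferences number of baselines drawn (without replacement,
#'   seeded) from the pool and averaged over.
#' @export
deepLiftShap <- function(model, sample, targetClass, referencePool,
                         nReferences = nrow(referencePool),
                         dropoutEnabled = FALSE, seed = 1L) {
  if (is.null(dim(referencePool)) || nrow(referencePool) < 1L)
    .stopf("'referencePool' must be a non-empty matrix of baselines")
  x <- .inputMatrix(model, sample)[1L, ]
  masks <- .explainMasks(model, dropoutEnabled, seed)
  refs <- drawReferences(referencePool, nReferences,
                         seed = deriveSeed(seed, 700))
  s <- .avgOverReferences(model, x, refs,
                          .targetIndex(model, targetClass),
                          .deepliftCore, masks)
  .wrapAttribution(s, model, "DeepLiftShap", targetClass,
                   reference = sprintf("pool[%d]", nReferences))
}

#' @rdname explainers
#' @param variant `"gradcam"` (channel weights are spatially averaged
#'   gradients) or `"gradcam++"` (closed-form alpha-weighted positive
#'   gradients).
#' @export
guidedGradCam <- function(model, sample, targetClass,
                          variant = c("gradcam", "gradcam++"),
                          dropoutEnabled = FALSE, seed = 1L) {
  variant <- match.arg(variant)
  masks <- .explainMasks(model, dropoutEnabled, seed)
  s <- .gradcamCore(model, .inputMatrix(model, sample)[1L, ],
                    .targetIndex(model, targetClass), variant, masks)
  .wrapAttribution(s, model,
                   if (variant == "gradcam") "GuidedGradCam"
                   else "GuidedGradCam++", targetClass)
}

#' Dispatch an explainer by identifier
#'
#' Uniform front end over the eight explainers; see [explainers]. With
#' `dropoutEnabled`, each call draws a fresh seeded dropout mask; with it
#' disabled, calls are deterministic.
#'
#' @param model a trained [TissueClassifier-class].
#' @param sample gene-expression vector.
#' @param explainerId one of `"Saliency"`, `"InputXGradient"`,
#'   `"GuidedBackprop"`, `"IntegratedGradients"`, `"DeepLift"`,
#'   `"DeepLiftShap"`, `"GuidedGradCam"`, `"GuidedGradCam++"`.
#' @param targetClass class whose score is attributed.
#' @param reference baseline vector for IntegratedGradients/DeepLift.
#' @param referencePool baseline pool for DeepLiftShap, or for
#'   IntegratedGradients/DeepLift when `nReferences > 1` (the attribution
#'   is then averaged over `nReferences` drawn baselines).
#' @param nSteps IntegratedGradients quadrature steps.
#' @param nReferences number of pool baselines to average over.
#' @param dropoutEnabled,seed dropout-mask control.
#' @param signed signed Saliency variant.
#' @return An [Attribution-class].
#' @export
explain <- function(model, sample, explainerId, targetClass,
                    reference = NULL, referencePool = NULL, nSteps = 50L,
                    nReferences = 1L, dropoutEnabled = FALSE, seed = 1L,
                    signed = FALSE) {
  if (!explainerId %in% .explainerIds)
    .stopf("unknown explainer '%s'; valid: %s", explainerId,
           paste(.explainerIds, collapse = ", "))
  if (explainerId %in% c("GuidedGradCam", "GuidedGradCam++") &&
      model@arch != "CNN")
    .stopf("%s applies to CNN models only", explainerId)
  x <- .inputMatrix(model, sample)[1L, ]
  k <- .targetIndex(model, targetClass)
  masks <- .explainMasks(model, dropoutEnabled, seed)
  needsRef <- explainerId %in% c("IntegratedGradients", "DeepLift")
  if (needsRef && !is.null(referencePool) && nReferences >= 1L) {
    refs <- drawReferences(referencePool, nReferences,
                           seed = deriveSeed(seed, 700))
    core <- if (explainerId == "DeepLift") .deepliftCore
            else function(m, xx, rr, tt, msk) .igCore(m, xx, rr, tt,
                                                      nSteps, msk)
    s <- .avgOverReferences(model, x, refs, k, core, masks)
    return(.wrapAttribution(s, model, explainerId, targetClass,
                            reference = sprintf("pool[%d]", nReferences)))
  }
  if (needsRef && is.null(reference)) reference <- numeric(length(x))
  s <- switch(explainerId,
    Saliency = .saliencyCore(model, x, k, masks, signed),
    InputXGradient = .inputXGradientCore(model, x, k, masks),
    GuidedBackprop = .guidedBackpropCore(model, x, k, masks),
    IntegratedGradients = .igCore(model, x, reference, k,
                                  as.integer(nSteps), masks),
    DeepLift = .deepliftCore(model, x, reference, k, masks),
    DeepLiftShap = {
      if (is.null(referencePool))
        .stopf("DeepLiftShap requires 'referencePool'")
      refs <- drawReferences(referencePool, max(nReferences, 1L),
                             seed = deriveSeed(seed, 700))
      .avgOverReferences(model, x, refs, k, .deepliftCore, masks)
    },
    `GuidedGradCam` = .gradcamCore(model, x, k, "gradcam", masks),
    `GuidedGradCam++` = .gradcamCore(model, x, k, "gradcam++", masks))
  .wrapAttribution(s, model, explainerId, targetClass,
                   reference = if (needsRef ||
                                   explainerId == "DeepLiftShap")
                     "vector" else "none")
}
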