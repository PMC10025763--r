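#' Per-gene expression mean and standard deviation
#'
#' Computes each gene's mean and sample standard deviation of log2(TPM+1)
#' values over the scoped samples: all tissues (the "universal" scope) or a
#' single tissue (the "specific" scope).
#'
#' @param cohort a [TranscriptomeCohort-class].
#' @param tissue optional tissue label restricting the scope.
#' @return data.frame(gene, mu, sigma) with attribute `"scope"`.
#' @export
geneStats <- function(cohort, tissue = NULL) {
  v <- exprValues(cohort)
  if (!is.null(tissue)) {
    keep <- tissueLabels(cohort) == tissue
    if (!any(keep)) .stopf("unknown tissue '%s'", tissue)
    v <- v[, keep, drop = FALSE]
  }
  out <- data.frame(gene = rownames(v), mu = rowMeans(v),
                    sigma = apply(v, 1L, sd), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "scope") <- if (is.null(tissue)) "all" else tissue
  out
}

#' Specification of a baseline reference for attribution
#'
#' Four reference kinds are supported for the difference-from-reference
#' explainers (DeepLIFT, DeepLiftShap, IntegratedGradients):
#' \describe{
#'   \item{zero}{every gene set to 0 (the "black image" baseline).}
#'   \item{normal}{i.i.d. truncated N(0, 1) restricted to \[0, 1\].}
#'   \item{universal}{per-gene truncated N(mu_i, sigma_i) with statistics
#'     taken over samples from all tissues.}
#'   \item{specific}{as universal, but statistics from one tissue only.}
#' }
#' For universal/specific, `boundMode` selects the truncation interval:
#' `"literal"` restricts values between 0 and sigma_i;
#' `"symmetric"` (default) uses \[max(0, mu_i - sigma_i), mu_i + sigma_i\],
#' which keeps references near realistic expression levels. The chosen
#' mode travels with the `ReferenceSpec` so downstream metadata is
#' explicit.
#'
#' @param kind one of "zero", "normal", "universal", "specific".
#' @param poolSize number of reference vectors in a pool (default 2000).
#' @param tissue tissue label; required exactly when `kind = "specific"`.
#' @param seed integer seed.
#' @param boundMode "symmetric" or "literal".
#' @return list of class `"ReferenceSpec"`.
#' @export
referenceSpec <- function(kind = c("zero", "normal", "universal",
                                   "specific"),
                          poolSize = 2000L, tissue = NULL, seed = 1L,
                          boundMode = c("symmetric", "literal")) {
  kind <- match.arg(kind)
  boundMode <- match.arg(boundMode)
  .assertCount(poolSize, "poolSize")
  if (kind == "specific" && is.null(tissue))
    .stopf("'tissue' is required for kind = \"specific\"")
  if (kind != "specific" && !is.null(tissue))
    .stopf("'tissue' is only meaningful for kind = \"specific\"")
  structure(list(kind = kind, poolSize = as.integer(poolSize),
                 tissue = tissue, seed = as.integer(seed),
                 boundMode = boundMode),
            class = "ReferenceSpec")
}

# inverse-CDF sampling of truncated N(mu, sigma) on [lo, hi]; vectorized
# over genes. Degenerate intervals or far-tail truncation collapse to the
# nearest admissible value of mu.
.rtruncnorm <- function(n, mu, sigma, lo, hi) {
  mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  out <- pmin(pmax(mu, lo), hi)
  ok <- sigma > 0 & hi > lo
  if (any(ok)) {
    pLo <- pnorm(lo[ok], mu[ok], sigma[ok])
    pHi <- pnorm(hi[ok], mu[ok], sigma[ok])
    width <- pHi - pLo
    u <- runif(sum(ok))
    val <- qnorm(pLo + u * width, mu[ok], sigma[ok])
    # far-tail truncation: CDF width underflows, fall back to the clamp
    bad <- width < 1e-12 | !is.finite(val)
    val[bad] <- out[ok][bad]
    out[ok] <- pmin(pmax(val, lo[ok]), hi[ok])
  }
  out
}

.refBounds <- function(spec, stats) {
  switch(spec$boundMode,
    literal = list(lo = rep(0, nrow(stats)), hi = stats$sigma),
    symmetric = list(lo = pmax(0, stats$mu - stats$sigma),
                     hi = stats$mu + stats$sigma))
}

#' Draw a single reference vector
#'
#' @param spec a [referenceSpec()].
#' @param stats a [geneStats()] table (required for universal/specific; the
#'   scope must match: "all" for universal, the named tissue for specific).
#' @param nGenes number of genes (required for zero/normal when `stats` is
#'   not given).
#' @param seed overrides `spec$seed`.
#' @return Numeric reference vector on the log2(TPM+1) scale.
#' @export
makeReference <- function(spec, stats = NULL, nGenes = NULL, seed = NULL) {
  stopifnot(inherits(spec, "ReferenceSpec"))
  seed <- seed %||% spec$seed
  if (spec$kind %in% c("universal", "specific")) {
    if (is.null(stats)) .stopf("'stats' is required for kind '%s'",
                               spec$kind)
    scope <- attr(stats, "scope")
    want <- if (spec$kind == "universal") "all" else spec$tissue
    if (!is.null(scope) && !identical(scope, want))
      .stopf("stats scope '%s' does not match reference kind '%s'",
             scope, spec$kind)
    nGenes <- nrow(stats)
  }
  if (is.null(nGenes)) nGenes <- nrow(stats)
  if (is.null(nGenes)) .stopf("'nGenes' or 'stats' must be supplied")
  out <- switch(spec$kind,
    zero = numeric(nGenes),
    normal = .withSeed(seed, .rtruncnorm(nGenes, 0, 1, 0, 1)),
    {
      b <- .refBounds(spec, stats)
      .withSeed(seed,
                .rtruncnorm(nGenes, stats$mu, stats$sigma, b$lo, b$hi))
    })
  if (!is.null(stats)) names(out) <- stats$gene
  out
}

#' Build a pool of reference vectors
#'
#' For `kind = "zero"` the pool repeats the same all-zero reference
#' `poolSize` times; otherwise each row is an independent draw.
#'
#' @inheritParams makeReference
#' @return `poolSize x nGenes` matrix, one reference per row, with the
#'   spec attached as attribute `"spec"`.
#' @export
buildReferencePool <- function(spec, stats = NULL, nGenes = NULL) {
  stopifnot(inherits(spec, "ReferenceSpec"))
  rows <- lapply(seq_len(spec$poolSize), function(i)
    makeReference(spec, stats, nGenes,
                  seed = if (spec$kind == "zero") spec$seed
                         else deriveSeed(spec$seed, 600, i)))
  pool <- do.call(rbind, rows)
  attr(pool, "spec") <- spec
  pool
}

#' Draw reference rows from a pool without replacement
#'
#' @param pool matrix from [buildReferencePool()].
#' @param n number of references to draw.
#' @param seed integer seed.
#' @return `n x nGenes` matrix.
#' @export
drawReferences <- function(pool, n, seed = 1L) {
  if (n > nrow(pool))
    .stopf("cannot draw %d references from a pool of %d", n, nrow(pool))
  pick <- .withSeed(seed, sample.int(nrow(pool), n))
  pool[pick, , drop = FALSE]
}
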