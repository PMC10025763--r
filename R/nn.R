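# Internal layer framework.
#
# Tensors: MLP stages use N x F matrices; CNN stages use N x H x W x C
# arrays. Everything is double precision so reverse-mode gradients can be
# checked against central finite differences to tight tolerances.
#
# Layer types: togrid, conv, maxpool, bnorm, relu, dropout, gap, dense.
# Each layer is a plain list with a `type` field plus parameters. Forward
# returns list(out, cache, layer); backward consumes the cache and supports
# three propagation modes: "gradient" (plain reverse mode), "guided"
# (guided backpropagation: ReLU additionally zeroes negative upstream
# signal), and a separate DeepLIFT multiplier walk (.deepliftMultipliers).

.lyDense <- function(nin, nout) {
  list(type = "dense",
       W = matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout),
       b = numeric(nout))
}

.lyBnorm <- function(nf, scope = c("feature", "channel")) {
  list(type = "bnorm", scope = match.arg(scope), gamma = rep(1, nf),
       beta = numeric(nf), rm = numeric(nf), rv = rep(1, nf),
       eps = 1e-5, momentum = 0.1)
}

.lyConv <- function(kh, kw, cin, cout) {
  fanIn <- kh * kw * cin
  list(type = "conv", kh = kh, kw = kw, cin = cin, cout = cout,
       W = array(rnorm(fanIn * cout, 0, sqrt(2 / fanIn)),
                 c(kh, kw, cin, cout)),
       b = numeric(cout))
}

# ---- batch-norm core on an N x F matrix -----------------------------------

.bnormFwdMat <- function(layer, x, mode) {
  if (mode == "train") {
    mu <- colMeans(x)
    v <- colMeans(x^2) - mu^2
    invstd <- 1 / sqrt(v + layer$eps)
    xhat <- sweep(sweep(x, 2, mu), 2, invstd, `*`)
    m <- layer$momentum
    layer$rm <- (1 - m) * layer$rm + m * mu
    layer$rv <- (1 - m) * layer$rv + m * v
    out <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
    list(out = out, cache = list(xhat = xhat, invstd = invstd,
                                 mode = "train"), layer = layer)
  } else {
    invstd <- 1 / sqrt(layer$rv + layer$eps)
    scale <- layer$gamma * invstd
    out <- sweep(sweep(x, 2, scale, `*`), 2,
                 layer$beta - layer$rm * scale, `+`)
    list(out = out, cache = list(scale = scale, mode = "eval",
                                 x = x), layer = layer)
  }
}

.bnormBwdMat <- function(layer, cache, dout, paramGrads) {
  if (cache$mode == "eval") {
    dx <- sweep(dout, 2, cache$scale, `*`)
    pg <- if (paramGrads) {
      xhat <- sweep(cache$x, 2, layer$rm)
      xhat <- sweep(xhat, 2, 1 / sqrt(layer$rv + layer$eps), `*`)
      list(gamma = colSums(dout * xhat), beta = colSums(dout))
    }
    return(list(dx = dx, pg = pg))
  }
  n <- nrow(dout)
  xhat <- cache$xhat
  dgamma <- colSums(dout * xhat)
  dbeta <- colSums(dout)
  t1 <- sweep(dout * n, 2, dbeta)
  t1 <- t1 - sweep(xhat, 2, dgamma, `*`)
  dx <- sweep(t1, 2, layer$gamma * cache$invstd / n, `*`)
  list(dx = dx,
       pg = if (paramGrads) list(gamma = dgamma, beta = dbeta))
}

# ---- conv im2col helpers --------------------------------------------------

.convIdx <- function(H, W, C, kh, kw) {
  outH <- H - kh + 1L
  outW <- W - kw + 1L
  dh <- rep(seq_len(kh), times = kw * C)
  dw <- rep(rep(seq_len(kw), each = kh), times = C)
  cc <- rep(seq_len(C), each = kh * kw)
  pOff <- (dh - 1L) + H * (dw - 1L) + H * W * (cc - 1L)
  oh <- rep(seq_len(outH), times = outW)
  ow <- rep(seq_len(outW), each = outH)
  oOff <- oh + H * (ow - 1L)
  list(idx = outer(pOff, oOff, `+`), outH = outH, outW = outW)
}

.convFwd <- function(layer, x) {
  d <- dim(x)
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  ci <- .convIdx(H, W, C, layer$kh, layer$kw)
  khkwC <- layer$kh * layer$kw * C
  M <- matrix(aperm(x, c(2, 3, 4, 1)), H * W * C, N)
  P <- M[as.vector(ci$idx), , drop = FALSE]
  dim(P) <- c(khkwC, ci$outH * ci$outW * N)
  W2 <- matrix(layer$W, khkwC, layer$cout)
  O <- crossprod(W2, P) + layer$b
  dim(O) <- c(layer$cout, ci$outH, ci$outW, N)
  list(out = aperm(O, c(4, 2, 3, 1)),
       cache = list(P = P, ci = ci, dims = d))
}

.convBwd <- function(layer, cache, dout, paramGrads) {
  d <- cache$dims
  N <- d[1L]; H <- d[2L]; W <- d[3L]; C <- d[4L]
  ci <- cache$ci
  khkwC <- layer$kh * layer$kw * C
  dOm <- matrix(aperm(dout, c(4, 2, 3, 1)), layer$cout,
                ci$outH * ci$outW * N)
  W2 <- matrix(layer$W, khkwC, layer$cout)
  dP <- W2 %*% dOm
  dim(dP) <- c(khkwC * ci$outH * ci$outW, N)
  rs <- rowsum(dP, group = as.vector(ci$idx))
  dM <- matrix(0, H * W * C, N)
  dM[as.integer(rownames(rs)), ] <- rs
  dx <- aperm(array(dM, c(H, W, C, N)), c(4, 1, 2, 3))
  pg <- if (paramGrads) {
    dW <- tcrossprod(cache$P, dOm)
    dim(dW) <- dim(layer$W)
    list(W = dW, b = rowSums(dOm))
  }
  list(dx = dx, pg = pg)
}

# ---- single layer forward -------------------------------------------------

.layerForward <- function(layer, x, mode, mask = NULL) {
  switch(layer$type,
    dense = {
      out <- x %*% layer$W
      out <- sweep(out, 2, layer$b, `+`)
      list(out = out, cache = list(x = x), layer = layer)
    },
    bnorm = {
      if (layer$scope == "feature") {
        r <- .bnormFwdMat(layer, x, mode)
        r$cache$shape <- NULL
        r
      } else {
        d <- dim(x)
        xm <- x; dim(xm) <- c(d[1L] * d[2L] * d[3L], d[4L])
        r <- .bnormFwdMat(layer, xm, mode)
        out <- r$out; dim(out) <- d
        r$cache$shape <- d
        list(out = out, cache = r$cache, layer = r$layer)
      }
    },
    relu = list(out = pmax(x, 0), cache = list(x = x), layer = layer),
    dropout = {
      if (mode == "train") {
        keep <- array(as.numeric(runif(length(x)) >= layer$p), dim(x) %||%
                        c(nrow(x), ncol(x)))
        sc <- keep / (1 - layer$p)
        list(out = x * sc, cache = list(sc = sc), layer = layer)
      } else if (!is.null(mask)) {
        sc <- .broadcastMask(mask / (1 - layer$p), x)
        list(out = x * sc, cache = list(sc = sc), layer = layer)
      } else {
        list(out = x, cache = list(sc = NULL), layer = layer)
      }
    },
    conv = {
      r <- .convFwd(layer, x)
      list(out = r$out, cache = r$cache, layer = layer)
    },
    maxpool = {
      d <- dim(x)
      k <- layer$k
      outH <- d[2L] %/% k; outW <- d[3L] %/% k
      if (outH < 1L || outW < 1L)
        .stopf("feature map %dx%d too small for max-pooling with kernel %d",
               d[2L], d[3L], k)
      cur <- NULL; arg <- NULL
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        cand <- x[, seq(di, by = k, length.out = outH),
                  seq(dj, by = k, length.out = outW), , drop = FALSE]
        code <- (di - 1L) * k + dj
        if (is.null(cur)) {
          cur <- cand
          arg <- array(code, dim(cand))
        } else {
          upd <- cand > cur
          cur[upd] <- cand[upd]
          arg[upd] <- code
        }
      }
      list(out = cur, cache = list(arg = arg, dims = d), layer = layer)
    },
    gap = {
      d <- dim(x)
      a3 <- array(x, c(d[1L], d[2L] * d[3L], d[4L]))
      out <- colMeans(aperm(a3, c(2, 1, 3)))
      dim(out) <- c(d[1L], d[4L])
      list(out = out, cache = list(dims = d), layer = layer)
    },
    togrid = {
      S <- layer$side
      N <- nrow(x)
      vperm <- x[, layer$geneOrder, drop = FALSE]
      vpad <- cbind(vperm, matrix(0, N, S * S - ncol(vperm)))
      out <- array(vpad[, layer$colperm, drop = FALSE], c(N, S, S, 1L))
      list(out = out, cache = list(N = N), layer = layer)
    },
    .stopf("unknown layer type '%s'", layer$type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Broadcast a per-unit dropout mask (vector for matrices, H x W x C array
# for feature maps) across the batch dimension.
.broadcastMask <- function(mask, x) {
  if (is.matrix(x)) {
    matrix(mask, nrow(x), ncol(x), byrow = TRUE)
  } else {
    array(rep(as.vector(mask), each = dim(x)[1L]), dim(x))
  }
}

# ---- single layer backward ------------------------------------------------

.layerBackward <- function(layer, cache, dout, mode = "gradient",
                           paramGrads = FALSE) {
  switch(layer$type,
    dense = list(
      dx = tcrossprod(dout, layer$W),
      pg = if (paramGrads) list(W = crossprod(cache$x, dout),
                                b = colSums(dout))),
    bnorm = {
      if (layer$scope == "feature") {
        .bnormBwdMat(layer, cache, dout, paramGrads)
      } else {
        d <- cache$shape
        dm <- dout; dim(dm) <- c(d[1L] * d[2L] * d[3L], d[4L])
        r <- .bnormBwdMat(layer, cache, dm, paramGrads)
        dim(r$dx) <- d
        r
      }
    },
    relu = {
      g <- dout * (cache$x > 0)
      if (mode == "guided") g <- g * (dout > 0)
      list(dx = g, pg = NULL)
    },
    dropout = list(
      dx = if (is.null(cache$sc)) dout else dout * cache$sc, pg = NULL),
    conv = .convBwd(layer, cache, dout, paramGrads),
    maxpool = {
      d <- cache$dims
      k <- layer$k
      outH <- d[2L] %/% k; outW <- d[3L] %/% k
      dx <- array(0, d)
      for (di in seq_len(k)) for (dj in seq_len(k)) {
        code <- (di - 1L) * k + dj
        sel <- cache$arg == code
        rows <- seq(di, by = k, length.out = outH)
        cols <- seq(dj, by = k, length.out = outW)
        view <- dx[, rows, cols, , drop = FALSE]
        view[sel] <- dout[sel]
        dx[, rows, cols, ] <- view
      }
      list(dx = dx, pg = NULL)
    },
    gap = {
      d <- cache$dims
      hw <- d[2L] * d[3L]
      dxm <- dout[rep(seq_len(d[1L]), hw), , drop = FALSE] / hw
      list(dx = array(dxm, d), pg = NULL)
    },
    togrid = {
      S <- layer$side
      dm <- dout; dim(dm) <- c(cache$N, S * S)
      dvpad <- dm[, layer$invcolperm, drop = FALSE]
      dv <- dvpad[, seq_along(layer$geneOrder), drop = FALSE]
      dx <- matrix(0, cache$N, length(layer$geneOrder))
      dx[, layer$geneOrder] <- dv
      list(dx = dx, pg = NULL)
    },
    .stopf("unknown layer type '%s'", layer$type))
}

# ---- whole network --------------------------------------------------------

.modelForward <- function(model, X, mode = "eval", masks = NULL,
                          keepCache = FALSE) {
  layers <- model@layers
  caches <- if (keepCache) vector("list", length(layers))
  x <- X
  for (i in seq_along(layers)) {
    r <- .layerForward(layers[[i]], x, mode,
                       mask = if (!is.null(masks)) masks[[i]])
    x <- r$out
    layers[[i]] <- r$layer
    if (keepCache) caches[[i]] <- r$cache
  }
  list(scores = x, caches = caches, layers = layers)
}

# Backward pass from a seed gradient on the pre-softmax scores.
# `stopAfter = i` returns the gradient w.r.t. the *output* of layer i
# (used by Grad-CAM); otherwise the gradient w.r.t. the network input.
.modelBackward <- function(model, caches, dscores, mode = "gradient",
                           paramGrads = FALSE, stopAfter = 0L) {
  layers <- model@layers
  g <- dscores
  pgs <- if (paramGrads) vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    if (i == stopAfter) break
    r <- .layerBackward(layers[[i]], caches[[i]], g, mode, paramGrads)
    g <- r$dx
    if (paramGrads) pgs[i] <- list(r$pg)
  }
  list(grad = g, paramGrads = pgs)
}

# DeepLIFT rescale-rule multipliers. Both caches must come from eval-mode
# forward passes that shared dropout masks. Linear/affine stages propagate
# multipliers exactly like gradients; each ReLU uses the unit-wise
# delta-output / delta-input ratio, falling back to the local gradient when
# |delta-input| < tol. Max-pooling is not representable as an affine or
# unit-wise-rescaled stage, so it is rejected.
.deepliftMultipliers <- function(model, cacheX, cacheR, dscores,
                                 tol = 1e-7) {
  layers <- model@layers
  m <- dscores
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    m <- switch(ly$type,
      dense = tcrossprod(m, ly$W),
      bnorm = {
        if (ly$scope == "feature") {
          sweep(m, 2, cacheX[[i]]$scale, `*`)
        } else {
          d <- dim(m)
          mm <- m; dim(mm) <- c(prod(d[1:3]), d[4L])
          mm <- sweep(mm, 2, cacheX[[i]]$scale, `*`)
          dim(mm) <- d
          mm
        }
      },
      relu = {
        dx <- cacheX[[i]]$x - cacheR[[i]]$x
        dy <- pmax(cacheX[[i]]$x, 0) - pmax(cacheR[[i]]$x, 0)
        mult <- ifelse(abs(dx) >= tol, dy / ifelse(abs(dx) >= tol, dx, 1),
                       as.numeric(cacheX[[i]]$x > 0))
        m * mult
      },
      dropout = if (is.null(cacheX[[i]]$sc)) m else m * cacheX[[i]]$sc,
      conv = .convBwd(ly, cacheX[[i]], m, FALSE)$dx,
      gap = .layerBackward(ly, cacheX[[i]], m)$dx,
      togrid = .layerBackward(ly, cacheX[[i]], m)$dx,
      maxpool = .stopf(paste0(
        "DeepLIFT rescale rule does not support max-pooling layers; ",
        "use a gradient-based explainer for CNN models")),
      .stopf("DeepLIFT: unsupported layer type '%s'", ly$type))
  }
  m
}
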