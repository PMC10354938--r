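#' @name attention
#' @title Masked axial attention and transformer blocks
#' @description
#' The distance weight mask, axial factorized attention, and the two
#' transformer block variants (standard dense attention and masked axial
#' attention). A token grid is a `[H, W, C, N]` feature map in which every
#' spatial cell is one attention token; tokens are flattened row-major
#' (token `t = (i-1)*W + j` for 1-based row `i`, column `j`).
NULL

#' Distance weight mask for axial attention
#'
#' Builds the square re-weighting matrix applied to axial correlation
#' entries. Entries are 1 on the diagonal, `k*d^2 - k*a^2 + 1` for token
#' distance `0 < d < a`, and 1 for `d >= a`: short-range correlations are
#' suppressed (strongly negative near the diagonal for the default `k`)
#' so that the parallel convolution branch, not the transformer, models
#' local context.
#'
#' @param n axis length (number of tokens along the masked axis).
#' @param k curvature hyperparameter (default 0.5).
#' @param a cutoff distance in tokens; entries at distance `>= a` are 1.
#'   Defaults to half the mask size.
#' @param clamp if `TRUE`, negative mask values are clamped at 0.
#' @return an `n x n` symmetric Toeplitz matrix.
#' @examples
#' buildDistanceMask(8, k = 0.5, a = 4)
#' @export
buildDistanceMask <- function(n, k = 0.5, a = ceiling(n / 2), clamp = FALSE) {
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("n must be a positive integer")
  n <- as.integer(n)
  if (a < 0) stop("a must be nonnegative")
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- matrix(1, n, n)
  mid <- d > 0 & d < a
  m[mid] <- k * d[mid]^2 - k * a^2 + 1
  if (clamp) m <- pmax(m, 0)
  m
}

#' Attention configuration
#'
#' @param embedDim channels per token; must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param mlpRatio hidden-width multiplier of the transformer MLP.
#' @param maskK curvature of the distance mask.
#' @param maskAFraction fraction of the axis length giving the mask cutoff
#'   `a = ceiling(maskAFraction * n)`.
#' @param clampMask clamp negative mask values at 0 (guards the sign flip
#'   when a raw correlation entry is negative; off by default, which keeps
#'   the mask exactly as defined).
#' @return a list of class `attentionConfig`.
#' @export
attentionConfig <- function(embedDim, heads = 2L, mlpRatio = 2,
                            maskK = 0.5, maskAFraction = 0.5,
                            clampMask = FALSE) {
  if (heads < 1L) stop("heads must be >= 1")
  if (embedDim %% heads != 0L) stop("embedDim must be divisible by heads")
  if (mlpRatio <= 0) stop("mlpRatio must be positive")
  structure(list(embedDim = as.integer(embedDim), heads = as.integer(heads),
                 mlpRatio = mlpRatio, maskK = maskK,
                 maskAFraction = maskAFraction, clampMask = clampMask),
            class = "attentionConfig")
}

maskFor <- function(n, cfg) {
  buildDistanceMask(n, k = cfg$maskK, a = ceiling(cfg$maskAFraction * n),
                    clamp = cfg$clampMask)
}

#' Axial mean profiles of a token grid
#'
#' Pools the token grid to one mean profile per axis: `fH[i, c, n]` is the
#' mean over the width axis, `fW[j, c, n]` the mean over the height axis.
#'
#' @param x token grid, `[H, W, C, N]` array.
#' @return list with `fH` (`[H, C, N]`) and `fW` (`[W, C, N]`).
#' @export
axialProfiles <- function(x) {
  d <- dim(x)
  if (length(d) != 4L || any(d[1:2] < 1L)) stop("x must be a non-empty [H,W,C,N] array")
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  fW <- colMeans(matrix(x, H, W * C * N))
  dim(fW) <- c(W, C, N)
  xp <- aperm(x, c(2, 1, 3, 4))
  fH <- colMeans(matrix(xp, W, H * C * N))
  dim(fH) <- c(H, C, N)
  list(fH = fH, fW = fW)
}

headCols <- function(h, headDim) (h - 1L) * headDim + seq_len(headDim)

#' Per-head axial correlation matrices
#'
#' Projects each axial profile with the learned query/key maps (shared
#' between the two axes) and forms the per-head correlation products
#' `Q_h K_h'` along each axis. The matrix products of this correlation
#' stage run through the package's multiply-accumulate counter, which the
#' complexity probes use.
#'
#' @param profiles result of [axialProfiles()].
#' @param cfg an [attentionConfig()].
#' @param params attention parameters (see [initAttentionParams()]).
#' @return list with `corrH` (`[H, H, heads, N]`) and `corrW`
#'   (`[W, W, heads, N]`).
#' @export
axialCorrelations <- function(profiles, cfg, params) {
  fH <- profiles$fH; fW <- profiles$fW
  C <- dim(fH)[2]; N <- dim(fH)[3]
  if (C != cfg$embedDim) stop("profile channels do not match embedDim")
  hd <- cfg$embedDim %/% cfg$heads
  corrAxis <- function(f) {
    n <- dim(f)[1]
    out <- array(0, c(n, n, cfg$heads, N))
    for (b in seq_len(N)) {
      fm <- f[, , b, drop = FALSE]
      dim(fm) <- c(n, C)
      q <- sweep(fm %*% params$Wq, 2L, params$bq, "+")
      k <- sweep(fm %*% params$Wk, 2L, params$bk, "+")
      for (h in seq_len(cfg$heads)) {
        cols <- headCols(h, hd)
        out[, , h, b] <- mmCounted(q[, cols, drop = FALSE],
                                   t(k[, cols, drop = FALSE]))
      }
    }
    out
  }
  list(corrH = corrAxis(fH), corrW = corrAxis(fW))
}

#' Assemble masked joint attention logits from axial correlations
#'
#' Applies the distance masks elementwise to the per-axis correlations and
#' reconnects the two axes into joint token-pair logits: the logit between
#' token `(i, j)` and token `(i', j')` is the product
#' `(maskH * corrH)[i, i'] x (maskW * corrW)[j, j']`, laid out with
#' row-major token flattening. The separable product is materialized as a
#' Kronecker product per head.
#'
#' @param corr list with `corrH`, `corrW` as from [axialCorrelations()].
#' @param maskH `H x H` distance mask; `maskW` likewise `W x W`.
#' @return `[H*W, H*W, heads, N]` array of joint logits.
#' @export
assembleMaskedLogits <- function(corr, maskH, maskW) {
  dH <- dim(corr$corrH); dW <- dim(corr$corrW)
  H <- dH[1]; W <- dW[1]; heads <- dH[3]; N <- dH[4]
  if (!all(dim(maskH) == c(H, H))) stop("maskH size does not match corrH")
  if (!all(dim(maskW) == c(W, W))) stop("maskW size does not match corrW")
  out <- array(0, c(H * W, H * W, heads, N))
  for (b in seq_len(N)) {
    for (h in seq_len(heads)) {
      mh <- maskH * corr$corrH[, , h, b]
      mw <- maskW * corr$corrW[, , h, b]
      # row-major token order t = (i-1)*W + j makes the joint logits the
      # Kronecker product of the H-axis and W-axis masked correlations
      out[, , h, b] <- kronecker(mh, mw)
    }
  }
  out
}

#' Initialize transformer block parameters
#'
#' @param cfg an [attentionConfig()].
#' @param initSd weight scale; defaults to `1/sqrt(embedDim)`.
#' @return named list of arrays: query/key/value/output projections, two
#'   layer norms, and the MLP.
#' @export
initAttentionParams <- function(cfg, initSd = NULL) {
  C <- cfg$embedDim
  hidden <- max(1L, as.integer(round(cfg$mlpRatio * C)))
  if (is.null(initSd)) initSd <- 1 / sqrt(C)
  rm <- function(a, b, sd) matrix(stats::rnorm(a * b, sd = sd), a, b)
  list(
    Wq = rm(C, C, initSd), bq = numeric(C),
    Wk = rm(C, C, initSd), bk = numeric(C),
    Wv = rm(C, C, initSd), bv = numeric(C),
    Wo = rm(C, C, initSd), bo = numeric(C),
    ln1g = rep(1, C), ln1b = numeric(C),
    ln2g = rep(1, C), ln2b = numeric(C),
    Wm1 = rm(C, hidden, initSd), bm1 = numeric(hidden),
    Wm2 = rm(hidden, C, 1 / sqrt(hidden)), bm2 = numeric(C)
  )
}

## ---- autodiff helpers specific to attention ------------------------------

# tokens of a grid, row-major: [H,W,C,N] -> [HW*N, C] with row t + (n-1)*HW
agTokens <- function(x) {
  d <- dim(agValue(x))
  x <- agAperm(x, c(2, 1, 3, 4))          # (W,H,C,N): vector index j + (i-1)W
  x <- agReshape(x, c(d[1] * d[2], d[3], d[4]))
  x <- agAperm(x, c(1, 3, 2))             # (HW, N, C)
  agReshape(x, c(d[1] * d[2] * d[4], d[3]))
}

agTokensToGrid <- function(x, H, W, N) {
  C <- dim(agValue(x))[2]
  x <- agReshape(x, c(H * W, N, C))
  x <- agAperm(x, c(1, 3, 2))
  x <- agReshape(x, c(W, H, C, N))
  agAperm(x, c(2, 1, 3, 4))
}

# slice sample n from an [A,B,N] tensor -> [A,B] matrix
agSliceSample <- function(x, n) {
  d <- dim(agValue(x))
  v <- agValue(x)[, , n, drop = FALSE]
  dim(v) <- d[1:2]
  agOp(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , n] <- g
    list(gx)
  })
}

agStackSamples <- function(lst) {
  d2 <- dim(agValue(lst[[1]]))
  N <- length(lst)
  v <- array(0, c(d2, N))
  for (n in seq_len(N)) v[, , n] <- agValue(lst[[n]])
  agOp(v, lst, function(g) {
    lapply(seq_len(N), function(n) {
      gn <- g[, , n, drop = FALSE]
      dim(gn) <- d2
      gn
    })
  })
}

agCbind <- function(lst) {
  ncols <- vapply(lst, function(t) ncol(agValue(t)), integer(1))
  v <- do.call(cbind, lapply(lst, agValue))
  ends <- cumsum(ncols)
  starts <- c(1L, ends[-length(ends)] + 1L)
  agOp(v, lst, function(g) {
    lapply(seq_along(lst), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# a %*% t(b)
agMatmulBt <- function(a, b) {
  av <- agValue(a); bv <- agValue(b)
  agOp(mmCounted(av, t(bv)), list(a, b), function(g) {
    list(g %*% bv, crossprod(g, av))
  })
}

# mean over the width axis: [H,W,C,N] -> [H,C,N]
agMeanOverW <- function(x) {
  d <- dim(agValue(x))
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  ap <- aperm(agValue(x), c(2, 1, 3, 4))
  v <- colMeans(matrix(ap, W, H * C * N))
  dim(v) <- c(H, C, N)
  agOp(v, list(x), function(g) {
    gx <- array(rep(as.vector(g) / W, each = W), c(W, H, C, N))
    list(aperm(gx, c(2, 1, 3, 4)))
  })
}

# mean over the height axis: [H,W,C,N] -> [W,C,N]
agMeanOverH <- function(x) {
  d <- dim(agValue(x))
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  v <- colMeans(matrix(agValue(x), H, W * C * N))
  dim(v) <- c(W, C, N)
  agOp(v, list(x), function(g) {
    gx <- array(rep(as.vector(g) / H, each = H), c(H, W, C, N))
    list(gx)
  })
}

# Kronecker product of two ag matrices (joint logits assembly)
agKron <- function(a, b) {
  av <- agValue(a); bv <- agValue(b)
  da <- dim(av); db <- dim(bv)
  agOp(kronecker(av, bv), list(a, b), function(g) {
    G <- array(g, c(db[1], da[1], db[2], da[2]))   # (j, i, j', i')
    Ga <- aperm(G, c(2, 4, 1, 3))                  # (i, i', j, j')
    dim(Ga) <- c(da[1] * da[2], db[1] * db[2])
    ga <- Ga %*% as.vector(bv)
    dim(ga) <- da
    Gb <- aperm(G, c(1, 3, 2, 4))                  # (j, j', i, i')
    dim(Gb) <- c(db[1] * db[2], da[1] * da[2])
    gb <- Gb %*% as.vector(av)
    dim(gb) <- db
    list(ga, gb)
  })
}

agGelu <- function(x) {
  v <- agValue(x)
  Phi <- stats::pnorm(v)
  agOp(v * Phi, list(x), function(g) {
    list(g * (Phi + v * stats::dnorm(v)))
  })
}

## ---- attention cores (autodiff) ------------------------------------------

# Masked axial multi-head self-attention on an ag token grid.
# Q/K come from pooled axial profiles (shared projections across axes),
# V from the full token sequence; per-head joint logits are the masked
# separable product, scaled by 1/sqrt(headDim) and softmaxed over keys.
agMaskedAxialMSA <- function(x, cfg, P) {
  d <- dim(agValue(x))
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  stopifnot(C == cfg$embedDim)
  hd <- C %/% cfg$heads
  maskH <- maskFor(H, cfg)
  maskW <- maskFor(W, cfg)
  fH <- agMeanOverW(x)
  fW <- agMeanOverH(x)
  scale <- 1 / sqrt(hd)
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    fHn <- agSliceSample(fH, n)
    fWn <- agSliceSample(fW, n)
    tokn <- agTokens(agOpSliceGrid(x, n))            # [HW, C]
    qH <- agLinear(fHn, P$Wq, P$bq); kH <- agLinear(fHn, P$Wk, P$bk)
    qW <- agLinear(fWn, P$Wq, P$bq); kW <- agLinear(fWn, P$Wk, P$bk)
    V <- agLinear(tokn, P$Wv, P$bv)
    heads <- vector("list", cfg$heads)
    for (h in seq_len(cfg$heads)) {
      cols <- headCols(h, hd)
      cH <- agMatmulBt(agCols(qH, cols), agCols(kH, cols))   # [H,H]
      cW <- agMatmulBt(agCols(qW, cols), agCols(kW, cols))   # [W,W]
      L <- agKron(agMul(cH, maskH), agMul(cW, maskW))        # [HW,HW]
      A <- agSoftmaxRows(agScale(L, scale))
      heads[[h]] <- agMatmul(A, agCols(V, cols))
    }
    outs[[n]] <- agLinear(agCbind(heads), P$Wo, P$bo)
  }
  tok <- agStackSamples(outs)                        # [HW, C, N]
  gridFromTokenStack(tok, H, W, N)
}

# Standard dense multi-head self-attention on an ag token grid.
agStandardMSA <- function(x, cfg, P) {
  d <- dim(agValue(x))
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  stopifnot(C == cfg$embedDim)
  hd <- C %/% cfg$heads
  scale <- 1 / sqrt(hd)
  outs <- vector("list", N)
  for (n in seq_len(N)) {
    tokn <- agTokens(agOpSliceGrid(x, n))
    Q <- agLinear(tokn, P$Wq, P$bq)
    K <- agLinear(tokn, P$Wk, P$bk)
    V <- agLinear(tokn, P$Wv, P$bv)
    heads <- vector("list", cfg$heads)
    for (h in seq_len(cfg$heads)) {
      cols <- headCols(h, hd)
      L <- agScale(agMatmulBt(agCols(Q, cols), agCols(K, cols)), scale)
      A <- agSoftmaxRows(L)
      heads[[h]] <- agMatmul(A, agCols(V, cols))
    }
    outs[[n]] <- agLinear(agCbind(heads), P$Wo, P$bo)
  }
  gridFromTokenStack(agStackSamples(outs), H, W, N)
}

# slice one sample of a grid: [H,W,C,N] -> [H,W,C,1]
agOpSliceGrid <- function(x, n) {
  d <- dim(agValue(x))
  v <- agValue(x)[, , , n, drop = FALSE]
  agOp(v, list(x), function(g) {
    gx <- array(0, d)
    gx[, , , n] <- g
    list(gx)
  })
}

gridFromTokenStack <- function(tok, H, W, N) {
  # tok: [HW, C, N] in row-major token order -> grid [H,W,C,N]
  C <- dim(agValue(tok))[2]
  x <- agAperm(tok, c(1, 3, 2))            # (HW, N, C)
  x <- agReshape(x, c(H * W * N, C))
  agTokensToGrid(x, H, W, N)
}

# Pre-norm transformer block (residual around both MSA and MLP):
#   zhat = MSA(LN(z)) + z ; z' = MLP(LN(zhat)) + zhat
agTransformerBlock <- function(x, cfg, P, kind = c("masked_axial", "standard")) {
  kind <- match.arg(kind)
  d <- dim(agValue(x))
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  if (any(!is.finite(agValue(x)))) stop("non-finite activations entering transformer block")
  tok <- agTokens(x)
  h1 <- agLayerNorm(tok, P$ln1g, P$ln1b)
  g1 <- agTokensToGrid(h1, H, W, N)
  att <- switch(kind,
                masked_axial = agMaskedAxialMSA(g1, cfg, P),
                standard = agStandardMSA(g1, cfg, P))
  z1 <- agAdd(tok, agTokens(att))
  h2 <- agLayerNorm(z1, P$ln2g, P$ln2b)
  m <- agLinear(agGelu(agLinear(h2, P$Wm1, P$bm1)), P$Wm2, P$bm2)
  z2 <- agAdd(z1, m)
  agTokensToGrid(z2, H, W, N)
}

## ---- plain-array surface --------------------------------------------------

wrapP <- function(params) lapply(params, agTensor, requires_grad = FALSE)

#' Masked axial multi-head self-attention
#'
#' The improved attention of the parallel transformer: queries and keys are
#' computed from axis-pooled profiles, correlations along each axis are
#' re-weighted by the distance mask, reconnected into joint token-pair
#' logits, softmaxed over keys with `1/sqrt(headDim)` scaling, and applied
#' to values computed from the full (unpooled) token sequence.
#'
#' @param x token grid `[H, W, C, N]` with `C == cfg$embedDim`.
#' @param cfg an [attentionConfig()].
#' @param params parameters from [initAttentionParams()].
#' @return token grid of the same shape.
#' @export
maskedAxialAttention <- function(x, cfg, params) {
  out <- agValue(agMaskedAxialMSA(agTensor(x), cfg, wrapP(params)))
  if (any(!is.finite(out))) stop("non-finite activations in masked axial attention")
  out
}

#' Standard dense multi-head self-attention
#'
#' @inheritParams maskedAxialAttention
#' @return token grid of the same shape.
#' @export
standardAttention <- function(x, cfg, params) {
  out <- agValue(agStandardMSA(agTensor(x), cfg, wrapP(params)))
  if (any(!is.finite(out))) stop("non-finite activations in attention")
  out
}

#' Transformer block (pre-norm residual form)
#'
#' `zhat = MSA(LN(z)) + z` followed by `z' = MLP(LN(zhat)) + zhat`, with the
#' MSA either standard dense attention or masked axial attention.
#'
#' @inheritParams maskedAxialAttention
#' @param kind `"standard"` or `"masked_axial"`.
#' @export
transformerBlock <- function(x, cfg, params, kind = c("masked_axial", "standard")) {
  kind <- match.arg(kind)
  agValue(agTransformerBlock(agTensor(x), cfg, wrapP(params), kind))
}

## ---- complexity probes ----------------------------------------------------

#' Measure multiply-accumulates of the query-key correlation stage
#'
#' Runs the actual correlation computation (axial factorized or standard
#' dense) on a random token grid with the matrix-product counter switched
#' on, and reports the multiply-accumulate count of the `Q K'` products.
#' The axial scheme scales as `O((H^2 + W^2) C)` against `O((HW)^2 C)` for
#' dense attention.
#'
#' @param H,W token grid extents.
#' @param cfg an [attentionConfig()].
#' @param kind `"axial"` or `"standard"`.
#' @return number of multiply-accumulate operations (a count, not a time).
#' @export
measureQkMacs <- function(H, W, cfg, kind = c("axial", "standard")) {
  kind <- match.arg(kind)
  C <- cfg$embedDim
  params <- initAttentionParams(cfg)
  x <- array(stats::rnorm(H * W * C), c(H, W, C, 1L))
  if (kind == "axial") {
    prof <- axialProfiles(x)
    macCounterReset()
    invisible(axialCorrelations(prof, cfg, params))
    macCounterRead()
  } else {
    tok <- matrix(aperm(x, c(2, 1, 3, 4)), H * W, C)
    q <- sweep(tok %*% params$Wq, 2L, params$bq, "+")
    k <- sweep(tok %*% params$Wk, 2L, params$bk, "+")
    hd <- C %/% cfg$heads
    macCounterReset()
    for (h in seq_len(cfg$heads)) {
      cols <- headCols(h, hd)
      invisible(mmCounted(q[, cols, drop = FALSE], t(k[, cols, drop = FALSE])))
    }
    macCounterRead()
  }
}
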