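#' @name layers
#' @title Differentiable network layers
#' @description
#' BLAS-backed layer kernels on `[H, W, C, N]` feature maps: 2-D convolution
#' (offset-loop formulation, one matrix product per kernel tap), max/average
#' pooling, bilinear upsampling, batch and layer normalization, and the
#' broadcasting gate products used by the fusion module. Each op carries its
#' analytic backward pass; the test suite validates all of them against
#' central finite differences.
#' @keywords internal
NULL

padSpatial <- function(x, p, fill = 0) {
  d <- dim(x)
  out <- array(fill, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

## ---- convolution ---------------------------------------------------------

# x: [H,W,Cin,N]; w: [kh,kw,Cin,Cout]; b: length Cout or NULL.
# Heavy lifting (im2col + GEMM, and the matching backward) happens in the
# compiled kernels of src/conv.cpp.
agConv2d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  x <- asAg(x); w <- asAg(w)
  xv <- x$value; wv <- w$value
  d <- dim(xv); kd <- dim(wv)
  stopifnot(length(d) == 4L, kd[3] == d[3])
  hasBias <- !is.null(b)
  if (hasBias) b <- asAg(b)
  y <- conv2dForwardCpp(xv, wv, if (hasBias) b$value else NULL,
                        as.integer(stride), as.integer(pad))
  parents <- if (hasBias) list(x, w, b) else list(x, w)
  agOp(y, parents, function(g) {
    bw <- conv2dBackwardCpp(xv, wv, g, as.integer(stride), as.integer(pad),
                            hasBias)
    if (hasBias) list(bw$gx, bw$gw, bw$gb) else list(bw$gx, bw$gw)
  })
}

## ---- pooling -------------------------------------------------------------

# 3x3 stride-2 max pool with 1-pixel padding (the classic residual-net stem
# pool). Ties go to the first kernel tap in row-major tap order.
agMaxPool3s2 <- function(x) {
  x <- asAg(x)
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- padSpatial(xv, 1L, fill = -Inf)
  Ho <- (H + 2 - 3) %/% 2 + 1L
  Wo <- (W + 2 - 3) %/% 2 + 1L
  best <- array(-Inf, c(Ho, Wo, C, N))
  win <- array(0L, c(Ho, Wo, C, N))
  k <- 0L
  for (ki in 1:3) {
    for (kj in 1:3) {
      k <- k + 1L
      xs <- xp[ki + 2 * (seq_len(Ho) - 1L), kj + 2 * (seq_len(Wo) - 1L), , , drop = FALSE]
      m <- xs > best
      best[m] <- xs[m]
      win[m] <- k
    }
  }
  agOp(best, list(x), function(g) {
    gxp <- array(0, dim(xp))
    k <- 0L
    for (ki in 1:3) {
      for (kj in 1:3) {
        k <- k + 1L
        ri <- ki + 2 * (seq_len(Ho) - 1L)
        ci <- kj + 2 * (seq_len(Wo) - 1L)
        gxp[ri, ci, , ] <- gxp[ri, ci, , , drop = FALSE] + g * (win == k)
      }
    }
    list(gxp[1 + seq_len(H), 1 + seq_len(W), , , drop = FALSE])
  })
}

# 2x2 stride-2 average pool (transformer-branch token downsampling)
agAvgPool2 <- function(x) {
  x <- asAg(x)
  xv <- x$value
  d <- dim(xv)
  stopifnot(d[1] %% 2 == 0, d[2] %% 2 == 0)
  o <- seq(1L, d[1], by = 2L); e <- o + 1L
  oc <- seq(1L, d[2], by = 2L); ec <- oc + 1L
  y <- (xv[o, oc, , , drop = FALSE] + xv[e, oc, , , drop = FALSE] +
        xv[o, ec, , , drop = FALSE] + xv[e, ec, , , drop = FALSE]) / 4
  agOp(y, list(x), function(g) {
    gx <- array(0, d)
    g4 <- g / 4
    gx[o, oc, , ] <- g4
    gx[e, oc, , ] <- g4
    gx[o, ec, , ] <- g4
    gx[e, ec, , ] <- g4
    list(gx)
  })
}

# global average pool: [H,W,C,N] -> [C,N]
agGlobalAvgPool <- function(x) {
  x <- asAg(x)
  d <- dim(x$value)
  HW <- d[1] * d[2]
  v <- colMeans(matrix(x$value, HW, d[3] * d[4]))
  dim(v) <- c(d[3], d[4])
  agOp(v, list(x), function(g) {
    gx <- array(rep(as.vector(g) / HW, each = HW), d)
    list(gx)
  })
}

# channel-axis mean and max: [H,W,C,N] -> [H,W,2,N] (fusion spatial gate input)
agChannelMeanMax <- function(x) {
  x <- asAg(x)
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- aperm(xv, c(1, 2, 4, 3))
  m <- matrix(xp, H * W * N, C)
  mu <- rowMeans(m)
  mx <- m[, 1]
  winner <- rep(1L, length(mx))
  if (C > 1) {
    for (c in 2:C) {
      upd <- m[, c] > mx
      mx[upd] <- m[upd, c]
      winner[upd] <- c
    }
  }
  out <- array(0, c(H, W, 2L, N))
  out[, , 1L, ] <- aperm(array(mu, c(H, W, N)), c(1, 2, 3))
  out[, , 2L, ] <- array(mx, c(H, W, N))
  agOp(out, list(x), function(g) {
    gmu <- as.vector(g[, , 1L, ])    # [H*W*N]
    gmx <- as.vector(g[, , 2L, ])
    gm <- matrix(gmu / C, H * W * N, C)
    gm[cbind(seq_along(winner), winner)] <-
      gm[cbind(seq_along(winner), winner)] + gmx
    dim(gm) <- c(H, W, N, C)
    list(aperm(gm, c(1, 2, 4, 3)))
  })
}

## ---- bilinear upsampling -------------------------------------------------

# 1-D bilinear interpolation matrix from `n` to `no` samples, half-pixel
# centre alignment (the common align_corners = FALSE convention)
bilinearMatrix <- function(n, no) {
  U <- matrix(0, no, n)
  s <- n / no
  for (i in seq_len(no)) {
    src <- (i - 0.5) * s - 0.5
    i0 <- floor(src)
    w1 <- 1 - (src - i0)
    lo <- min(max(i0, 0), n - 1)
    hi <- min(max(i0 + 1, 0), n - 1)
    U[i, lo + 1] <- U[i, lo + 1] + w1
    U[i, hi + 1] <- U[i, hi + 1] + (1 - w1)
  }
  U
}

# x2 bilinear upsampling as two separable interpolation products
agUpsample2 <- function(x) {
  x <- asAg(x)
  d <- dim(x$value)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  Uh <- bilinearMatrix(H, 2L * H)
  Uw <- bilinearMatrix(W, 2L * W)
  y1 <- Uh %*% matrix(x$value, H, W * C * N)
  dim(y1) <- c(2L * H, W, C, N)
  y1 <- aperm(y1, c(2, 1, 3, 4))
  y2 <- Uw %*% matrix(y1, W, 2L * H * C * N)
  dim(y2) <- c(2L * W, 2L * H, C, N)
  y <- aperm(y2, c(2, 1, 3, 4))
  agOp(y, list(x), function(g) {
    g2 <- aperm(g, c(2, 1, 3, 4))
    dim(g2) <- c(2L * W, 2L * H * C * N)
    g1 <- crossprod(Uw, g2)
    dim(g1) <- c(W, 2L * H, C, N)
    g1 <- aperm(g1, c(2, 1, 3, 4))
    dim(g1) <- c(2L * H, W * C * N)
    gx <- crossprod(Uh, g1)
    dim(gx) <- c(H, W, C, N)
    list(gx)
  })
}

## ---- normalization -------------------------------------------------------

# batch normalization over (H, W, N) per channel. `state` is a mutable
# environment holding running_mean / running_var, updated in training mode.
# Per-channel constants are applied through vector recycling over the
# [H*W, C, N] layout (a length H*W*C vector recycles across the batch).
agBatchNorm <- function(x, gamma, beta, state, training = TRUE,
                        momentum = 0.1, eps = 1e-5) {
  x <- asAg(x); gamma <- asAg(gamma); beta <- asAg(beta)
  xv <- x$value
  d <- dim(xv)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  HW <- H * W
  m <- HW * N
  perChannel <- function(v) {
    # reduce an [H,W,C,N] array to per-channel sums
    cn <- colSums(matrix(v, HW, C * N))
    rowSums(matrix(cn, C, N))
  }
  expand <- function(a) rep(a, each = HW)   # length HW*C, recycled over N
  if (training) {
    mu <- perChannel(xv) / m
    va <- pmax(perChannel(xv * xv) / m - mu * mu, 0)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    ub <- if (m > 1) va * m / (m - 1) else va
    state$running_var <- (1 - momentum) * state$running_var + momentum * ub
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  invstd <- 1 / sqrt(va + eps)
  a <- gamma$value * invstd
  y <- xv * expand(a) + expand(beta$value - a * mu)
  agOp(y, list(x, gamma, beta), function(g) {
    xhat <- xv * expand(invstd) - expand(mu * invstd)
    dgamma <- perChannel(g * xhat)
    dbeta <- perChannel(g)
    if (training) {
      dx <- (g - expand(dbeta / m) - xhat * expand(dgamma / m)) * expand(a)
    } else {
      dx <- g * expand(a)
    }
    list(dx, dgamma, dbeta)
  })
}

# layer normalization over the channel axis of a token matrix [tokens, C]
agLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- asAg(x); gamma <- asAg(gamma); beta <- asAg(beta)
  xv <- x$value
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  invstd <- 1 / sqrt(va + eps)
  xhat <- xc * invstd
  y <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  agOp(y, list(x, gamma, beta), function(g) {
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    gh <- sweep(g, 2L, gamma$value, "*")
    dx <- invstd * (gh - rowMeans(gh) - xhat * rowMeans(gh * xhat))
    list(dx, dgamma, dbeta)
  })
}

## ---- broadcasting gates --------------------------------------------------

# multiply [H,W,C,N] by a per-channel gate [C,N]
agMulChannelGate <- function(x, gate) {
  x <- asAg(x); gate <- asAg(gate)
  d <- dim(x$value)
  HW <- d[1] * d[2]
  gv <- rep(as.vector(gate$value), each = HW)
  xv <- x$value
  agOp(xv * gv, list(x, gate), function(g) {
    gg <- colSums(matrix(g * xv, HW, d[3] * d[4]))
    dim(gg) <- c(d[3], d[4])
    list(g * gv, gg)
  })
}

# multiply [H,W,C,N] by a single-channel spatial gate [H,W,1,N]
agMulSpatialGate <- function(x, gate) {
  x <- asAg(x); gate <- asAg(gate)
  d <- dim(x$value)
  gv <- gate$value[, , rep(1L, d[3]), , drop = FALSE]
  xv <- x$value
  agOp(xv * gv, list(x, gate), function(g) {
    gx <- g * gv
    gs <- g * xv
    gg <- array(0, c(d[1], d[2], 1L, d[4]))
    gg[, , 1L, ] <- rowSums(aperm(gs, c(1, 2, 4, 3)), dims = 3L)
    list(gx, gg)
  })
}

## ---- fused losses (logit-space, numerically stable) ----------------------

# elementwise binary cross-entropy from logits: softplus(z) - z*y
bceFromLogits <- function(z, y) {
  pmax(z, 0) - z * y + log1p(exp(-abs(z)))
}

agBceWithLogitsMean <- function(z, y) {
  z <- asAg(z)
  zv <- z$value
  n <- length(zv)
  v <- mean(bceFromLogits(zv, y))
  agOp(v, list(z), function(g) {
    p <- 1 / (1 + exp(-zv))
    list(g * (p - y) / n)
  })
}

# per-sample soft Dice loss from logits, averaged over the batch.
# z, y: [H,W,1,N]; factor-two numerator so that a perfect prediction
# attains 0 (an `asPrinted` switch drops the 2 for strict reproduction).
agDiceWithLogitsMean <- function(z, y, eps = 1, factorTwo = TRUE) {
  z <- asAg(z)
  zv <- z$value
  d <- dim(zv)
  HW <- d[1] * d[2]
  N <- d[4]
  p <- 1 / (1 + exp(-zv))
  pm <- matrix(p, HW, N)
  ym <- matrix(y, HW, N)
  S1 <- colSums(pm * ym)
  Sp <- colSums(pm)
  Sy <- colSums(ym)
  fac <- if (factorTwo) 2 else 1
  num <- fac * S1 + eps
  den <- Sp + Sy + eps
  v <- mean(1 - num / den)
  agOp(v, list(z), function(g) {
    # d/dp_i of (1 - num/den) = -(fac*y_i*den - num)/den^2
    dLdp <- -sweep(sweep(fac * ym, 2L, den, "*") - matrix(num, HW, N, byrow = TRUE),
                   2L, den^2, "/")
    dz <- dLdp * pm * (1 - pm) * (g / N)
    dim(dz) <- d
    list(dz)
  })
}

# per-image online hard-example mining BCE from logits: the per-pixel BCE is
# sorted descending (stable, ties by pixel index), the top keep_count pixels
# of each image are averaged, then images are averaged.
agOhemBceWithLogitsMean <- function(z, y, keepFraction = 0.25, minKept = 256L) {
  z <- asAg(z)
  zv <- z$value
  d <- dim(zv)
  HW <- d[1] * d[2] * d[3]
  N <- d[4]
  zm <- matrix(zv, HW, N)
  ym <- matrix(y, HW, N)
  l <- bceFromLogits(zm, ym)
  keep <- max(as.integer(minKept), as.integer(ceiling(keepFraction * HW)))
  keep <- min(keep, HW)
  sel <- matrix(FALSE, HW, N)
  tot <- 0
  for (n in seq_len(N)) {
    ord <- order(-l[, n], seq_len(HW))
    idx <- ord[seq_len(keep)]
    sel[idx, n] <- TRUE
    tot <- tot + mean(l[idx, n])
  }
  v <- tot / N
  agOp(v, list(z), function(g) {
    p <- 1 / (1 + exp(-zm))
    dz <- (p - ym) * sel / keep * (g / N)
    dim(dz) <- d
    list(dz)
  })
}
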