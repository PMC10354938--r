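# shared fixtures: small random tensors, loop oracles, and a relative-error
# helper used by the gradient checks

relErr <- function(a, b) max(abs(a - b)) / max(1e-6, max(abs(b)))

randGrid <- function(H, W, C, N = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(stats::rnorm(H * W * C * N), c(H, W, C, N))
}

# dense loop reference for masked axial attention (independent of the
# package's vectorized/Kronecker path)
denseMaskedAxialOracle <- function(x, cfg, P) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  hd <- C %/% cfg$heads
  maskH <- buildDistanceMask(H, cfg$maskK, ceiling(cfg$maskAFraction * H),
                             clamp = cfg$clampMask)
  maskW <- buildDistanceMask(W, cfg$maskK, ceiling(cfg$maskAFraction * W),
                             clamp = cfg$clampMask)
  out <- array(0, d)
  for (b in seq_len(N)) {
    fH <- matrix(0, H, C); fW <- matrix(0, W, C)
    for (i in seq_len(H)) for (c in seq_len(C)) fH[i, c] <- mean(x[i, , c, b])
    for (j in seq_len(W)) for (c in seq_len(C)) fW[j, c] <- mean(x[, j, c, b])
    qH <- sweep(fH %*% P$Wq, 2, P$bq, "+"); kH <- sweep(fH %*% P$Wk, 2, P$bk, "+")
    qW <- sweep(fW %*% P$Wq, 2, P$bq, "+"); kW <- sweep(fW %*% P$Wk, 2, P$bk, "+")
    tok <- matrix(0, H * W, C)
    for (i in seq_len(H)) for (j in seq_len(W)) tok[(i - 1) * W + j, ] <- x[i, j, , b]
    V <- sweep(tok %*% P$Wv, 2, P$bv, "+")
    headout <- NULL
    for (h in seq_len(cfg$heads)) {
      cols <- (h - 1) * hd + seq_len(hd)
      cH <- (qH[, cols, drop = FALSE] %*% t(kH[, cols, drop = FALSE])) * maskH
      cW <- (qW[, cols, drop = FALSE] %*% t(kW[, cols, drop = FALSE])) * maskW
      L <- matrix(0, H * W, H * W)
      for (i in seq_len(H)) for (j in seq_len(W))
        for (ip in seq_len(H)) for (jp in seq_len(W))
          L[(i - 1) * W + j, (ip - 1) * W + jp] <- cH[i, ip] * cW[j, jp]
      L <- L / sqrt(hd)
      A <- t(apply(L, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
      headout <- cbind(headout, A %*% V[, cols, drop = FALSE])
    }
    o <- sweep(headout %*% P$Wo, 2, P$bo, "+")
    for (i in seq_len(H)) for (j in seq_len(W)) out[i, j, , b] <- o[(i - 1) * W + j, ]
  }
  out
}

# the fixed desk-scale conditions used by the training checks
overfitSamples <- function(seed = 7L, n = 8L) {
  sc <- synthConfig(seed = seed)
  lapply(seq_len(n), function(i) genSample(sc, i))
}
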