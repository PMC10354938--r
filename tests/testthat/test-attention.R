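# the distance mask, axial pooling/correlation, logit assembly and the two
# attention variants, each against hand values or independent loop oracles

test_that("distance mask matches its closed-form branch rules", {
  # all distances >= a when a = 1: every entry is 1
  expect_equal(buildDistanceMask(3, k = 0.5, a = 1), matrix(1, 3, 3))
  m <- buildDistanceMask(8, k = 0.5, a = 4)
  expect_equal(diag(m), rep(1, 8))
  expect_equal(m[1, 3], 0.5 * 4 - 0.5 * 16 + 1)   # distance 2 -> -5
  expect_equal(m[1, 4], 0.5 * 9 - 8 + 1)          # distance 3 -> -2.5
  expect_equal(m[1, 5], 1)                        # distance 4 = a -> 1
  expect_error(buildDistanceMask(0), "positive")
})

test_that("distance mask is symmetric and Toeplitz for many (n, k, a)", {
  for (n in c(2, 5, 9, 16)) {
    for (k in c(0, 0.25, 0.5, 2)) {
      for (a in c(0, 1, 3, n / 2, n)) {
        m <- buildDistanceMask(n, k, a)
        expect_equal(m, t(m))
        d <- abs(outer(seq_len(n), seq_len(n), "-"))
        for (dd in unique(as.vector(d))) {
          expect_length(unique(m[d == dd]), 1L)
        }
      }
    }
  }
})

test_that("axial profiles equal the double-loop mean oracle", {
  # constant grid
  xc <- array(3.7, c(2, 5, 3, 1))
  pc <- axialProfiles(xc)
  expect_equal(as.vector(pc$fH), rep(3.7, 2 * 3))
  expect_equal(as.vector(pc$fW), rep(3.7, 5 * 3))
  # 1x2 grid with values 1, 3 along W
  x12 <- array(c(1, 3), c(1, 2, 1, 1))
  p12 <- axialProfiles(x12)
  expect_equal(as.vector(p12$fH), 2)
  expect_equal(as.vector(p12$fW), c(1, 3))
  # random grid vs loops
  set.seed(21)
  x <- randGrid(4, 4, 6, 2)
  pr <- axialProfiles(x)
  for (b in 1:2) for (c in 1:6) {
    for (i in 1:4) expect_equal(pr$fH[i, c, b], mean(x[i, , c, b]))
    for (j in 1:4) expect_equal(pr$fW[j, c, b], mean(x[, j, c, b]))
  }
})

test_that("axial correlations equal an explicit per-head matrix-product oracle", {
  set.seed(22)
  cfg <- attentionConfig(embedDim = 6, heads = 2)
  P <- initAttentionParams(cfg)
  x <- randGrid(3, 4, 6, 2)
  corr <- axialCorrelations(axialProfiles(x), cfg, P)
  expect_equal(dim(corr$corrH), c(3, 3, 2, 2))
  expect_equal(dim(corr$corrW), c(4, 4, 2, 2))
  pr <- axialProfiles(x)
  for (b in 1:2) {
    fH <- pr$fH[, , b]
    q <- sweep(fH %*% P$Wq, 2, P$bq, "+")
    k <- sweep(fH %*% P$Wk, 2, P$bk, "+")
    for (h in 1:2) {
      cols <- (h - 1) * 3 + 1:3
      expect_equal(corr$corrH[, , h, b],
                   q[, cols] %*% t(k[, cols]), tolerance = 1e-12)
    }
  }
  # zero profiles with zero biases give zero correlations
  P0 <- P; P0$bq <- 0 * P0$bq; P0$bk <- 0 * P0$bk
  z <- axialCorrelations(list(fH = array(0, c(3, 6, 1)), fW = array(0, c(4, 6, 1))),
                         cfg, P0)
  expect_true(all(z$corrH == 0) && all(z$corrW == 0))
  # H = 1: single 1x1 correlation = q . k of the lone projected row
  x1 <- randGrid(1, 4, 6, 1)
  pr1 <- axialProfiles(x1)
  c1 <- axialCorrelations(pr1, cfg, P)
  q1 <- sweep(matrix(pr1$fH[, , 1], 1, 6) %*% P$Wq, 2, P$bq, "+")
  k1 <- sweep(matrix(pr1$fH[, , 1], 1, 6) %*% P$Wk, 2, P$bk, "+")
  expect_equal(c1$corrH[1, 1, 1, 1], sum(q1[1:3] * k1[1:3]), tolerance = 1e-12)
})

test_that("assembled masked logits equal the four-index loop oracle exhaustively", {
  set.seed(23)
  for (H in 1:4) for (W in 1:4) for (heads in 1:2) {
    C <- 2 * heads
    corr <- list(corrH = array(rnorm(H * H * heads), c(H, H, heads, 1)),
                 corrW = array(rnorm(W * W * heads), c(W, W, heads, 1)))
    maskH <- buildDistanceMask(H, 0.5)
    maskW <- buildDistanceMask(W, 0.5)
    L <- assembleMaskedLogits(corr, maskH, maskW)
    for (h in seq_len(heads)) {
      for (i in 1:H) for (j in 1:W) for (ip in 1:H) for (jp in 1:W) {
        expect_equal(L[(i - 1) * W + j, (ip - 1) * W + jp, h, 1],
                     (maskH[i, ip] * corr$corrH[i, ip, h, 1]) *
                       (maskW[j, jp] * corr$corrW[j, jp, h, 1]),
                     tolerance = 1e-5)
      }
    }
  }
})

test_that("identity correlations under all-ones masks give indicator logits", {
  corr <- list(corrH = array(diag(3), c(3, 3, 1, 1)),
               corrW = array(diag(3), c(3, 3, 1, 1)))
  ones <- matrix(1, 3, 3)
  L <- assembleMaskedLogits(corr, ones, ones)
  expected <- diag(9)
  expect_equal(L[, , 1, 1], expected)
})

test_that("masked axial attention matches the dense loop reference", {
  set.seed(24)
  cfg <- attentionConfig(embedDim = 6, heads = 2)
  P <- initAttentionParams(cfg)
  x <- randGrid(4, 4, 6, 2)
  expect_equal(maskedAxialAttention(x, cfg, P),
               denseMaskedAxialOracle(x, cfg, P), tolerance = 1e-8)
  # single token: softmax over one key is 1, so out = Wo(V(token))
  x1 <- randGrid(1, 1, 6, 1)
  o1 <- maskedAxialAttention(x1, cfg, P)
  v <- sweep(matrix(x1[1, 1, , 1], 1, 6) %*% P$Wv, 2, P$bv, "+")
  expect_equal(as.vector(o1), as.vector(sweep(v %*% P$Wo, 2, P$bo, "+")),
               tolerance = 1e-10)
})

test_that("k = 0 and a <= 1 masks reproduce unmasked axial attention bit-for-bit", {
  set.seed(25)
  P <- initAttentionParams(attentionConfig(embedDim = 4, heads = 2))
  x <- randGrid(4, 4, 4, 1)
  cfgK0 <- attentionConfig(embedDim = 4, heads = 2, maskK = 0)
  cfgA1 <- attentionConfig(embedDim = 4, heads = 2, maskAFraction = 1 / 8)  # a = 1
  expect_true(all(buildDistanceMask(4, k = 0) == 1))
  outK0 <- maskedAxialAttention(x, cfgK0, P)
  outA1 <- maskedAxialAttention(x, cfgA1, P)
  expect_identical(outK0, outA1)
})

test_that("attention softmax rows sum to one", {
  set.seed(26)
  L <- matrix(rnorm(64, sd = 4), 8, 8)
  A <- axialseg:::agValue(axialseg:::agSoftmaxRows(axialseg:::agTensor(L)))
  expect_equal(rowSums(A), rep(1, 8), tolerance = 1e-5)
})

test_that("transformer block preserves shape and is identity at zero output projections", {
  set.seed(27)
  cfg <- attentionConfig(embedDim = 4, heads = 2)
  P <- initAttentionParams(cfg)
  x <- randGrid(3, 5, 4, 2)
  for (kind in c("standard", "masked_axial")) {
    expect_equal(dim(transformerBlock(x, cfg, P, kind)), dim(x))
  }
  P0 <- P
  P0$Wo <- 0 * P0$Wo; P0$bo <- 0 * P0$bo
  P0$Wm2 <- 0 * P0$Wm2; P0$bm2 <- 0 * P0$bm2
  expect_equal(transformerBlock(x, cfg, P0, "standard"), x, tolerance = 1e-12)
  expect_equal(transformerBlock(x, cfg, P0, "masked_axial"), x, tolerance = 1e-12)
  expect_error(transformerBlock(x, cfg, P, "swin"))
})

test_that("standard attention on a 2x2 grid matches a from-scratch single-head oracle", {
  set.seed(28)
  cfg <- attentionConfig(embedDim = 3, heads = 1)
  P <- initAttentionParams(cfg)
  x <- randGrid(2, 2, 3, 1)
  out <- standardAttention(x, cfg, P)
  tok <- matrix(0, 4, 3)
  for (i in 1:2) for (j in 1:2) tok[(i - 1) * 2 + j, ] <- x[i, j, , 1]
  Q <- sweep(tok %*% P$Wq, 2, P$bq, "+")
  K <- sweep(tok %*% P$Wk, 2, P$bk, "+")
  V <- sweep(tok %*% P$Wv, 2, P$bv, "+")
  L <- Q %*% t(K) / sqrt(3)
  A <- t(apply(L, 1, function(r) { e <- exp(r - max(r)); e / sum(e) }))
  ref <- sweep((A %*% V) %*% P$Wo, 2, P$bo, "+")
  for (i in 1:2) for (j in 1:2) {
    expect_equal(out[i, j, , 1], ref[(i - 1) * 2 + j, ], tolerance = 1e-10)
  }
})

test_that("axial correlation cost is far below dense attention cost at 32x32", {
  cfg <- attentionConfig(embedDim = 64, heads = 2)
  ax <- measureQkMacs(32, 32, cfg, "axial")
  st <- measureQkMacs(32, 32, cfg, "standard")
  expect_equal(ax, (32^2 + 32^2) * 64)     # (H^2 + W^2) * C
  expect_equal(st, (32 * 32)^2 * 64)       # (HW)^2 * C
  expect_lt(ax / st, 0.1)
})
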