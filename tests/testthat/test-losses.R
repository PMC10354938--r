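# hand-evaluated loss examples and the loss-suite invariants

test_that("binary cross-entropy matches hand values and a loop oracle", {
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(bceLoss(y, y), 1e-5)                       # perfect prediction
  expect_equal(bceLoss(matrix(0.5), matrix(1)), log(2), tolerance = 1e-12)
  set.seed(51)
  p <- matrix(runif(20), 4, 5)
  g <- matrix(rbinom(20, 1, 0.5), 4, 5)
  ref <- 0
  for (i in 1:4) for (j in 1:5) {
    ref <- ref - (g[i, j] * log(p[i, j]) + (1 - g[i, j]) * log(1 - p[i, j]))
  }
  expect_equal(bceLoss(p, g), ref / 20, tolerance = 1e-10)
  expect_error(bceLoss(matrix(0.5, 2, 2), matrix(1)), "mismatch")
})

test_that("dice loss matches hand values in the factor-two and printed forms", {
  y <- c(1, 1, 0, 0)
  expect_equal(diceLoss(y, y, eps = 1e-12), 0, tolerance = 1e-9)
  expect_equal(diceLoss(rep(0, 4), y, eps = 1e-12), 1, tolerance = 1e-6)
  expect_equal(diceLoss(rep(1, 4), y, eps = 1e-12), 1 - 4 / 6, tolerance = 1e-9)
  # the as-printed form (no factor 2) bottoms out at 0.5 for a perfect match
  expect_equal(diceLoss(y, y, eps = 1e-12, factorTwo = FALSE), 0.5, tolerance = 1e-9)
})

test_that("dice loss is invariant to joint pixel permutation", {
  set.seed(52)
  p <- runif(50)
  y <- rbinom(50, 1, 0.4)
  perm <- sample(50)
  expect_equal(diceLoss(p, y), diceLoss(p[perm], y[perm]), tolerance = 1e-14)
})

test_that("canny edges: empty and full masks give no edges; a square gives ~its perimeter", {
  z <- matrix(0, 32, 32)
  expect_equal(cannyEdgeMask(z), z)
  expect_equal(cannyEdgeMask(z + 1), z)
  cfg <- lossConfig(edgeDilation = 0L)
  for (s in c(12, 16, 20)) {
    m <- matrix(0, 48, 48)
    lo <- (48 - s) / 2 + 1
    m[lo:(lo + s - 1), lo:(lo + s - 1)] <- 1
    e <- cannyEdgeMask(m, cfg)
    expect_gt(sum(e), 4 * s * 0.8)
    expect_lt(sum(e), 4 * s * 1.2)
  }
  expect_error(cannyEdgeMask(matrix(0.3, 4, 4)), "binary")
})

test_that("canny edge band stays near the mask boundary", {
  set.seed(53)
  s <- genSample(synthConfig(seed = 99), 1)
  e <- cannyEdgeMask(s$mask)
  # every edge pixel must touch both classes within a small neighbourhood
  inside <- axialseg:::dilateBinary(s$mask, 2)
  outside <- axialseg:::dilateBinary(1 - s$mask, 2)
  expect_true(all(e * inside * outside == e))
})

test_that("ohem keeps the hardest pixels: keep-all equals plain BCE, top-half picks the losses it should", {
  set.seed(54)
  p <- runif(64)
  y <- rbinom(64, 1, 0.5)
  cfgAll <- lossConfig(ohemKeepFraction = 1, ohemMinKept = 1L)
  expect_equal(ohemBce(p, y, cfgAll), bceLoss(p, y), tolerance = 1e-12)
  # half the pixels at loss 0, half at loss c -> top-half mean is c
  cl <- 0.25
  pv <- c(rep(1, 32), rep(exp(-cl), 32))
  yv <- rep(1, 64)
  cfgHalf <- lossConfig(ohemKeepFraction = 0.5, ohemMinKept = 1L)
  expect_equal(ohemBce(pv, yv, cfgHalf), cl, tolerance = 1e-6)
  # deterministic under ties
  expect_identical(ohemBce(pv, yv, cfgHalf), ohemBce(pv, yv, cfgHalf))
  expect_error(ohemBce(numeric(0), numeric(0)), "empty")
})

test_that("ohem is monotone in the keep fraction for nonuniform losses", {
  set.seed(55)
  p <- runif(100)
  y <- rbinom(100, 1, 0.5)
  fr <- c(0.1, 0.25, 0.5, 0.75, 1)
  vals <- vapply(fr, function(f) {
    ohemBce(p, y, lossConfig(ohemKeepFraction = f, ohemMinKept = 1L))
  }, numeric(1))
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("weighted total matches hand arithmetic and is linear in each term", {
  w <- lossWeights()
  expect_equal(w$alpha + w$beta + w$gamma, 1)
  # components (ln 2, 1/3, ln 2): single-pixel constructions
  segP <- matrix(0.5); segY <- matrix(1)          # BCE = ln 2
  segP4 <- rep(1, 4); segY4 <- c(1, 1, 0, 0)      # Dice = 1/3
  cfg <- lossConfig(diceEpsilon = 1e-12, ohemKeepFraction = 1, ohemMinKept = 1L)
  tl <- totalLoss(segP, segY, segP, segY, weights = w, cfg = cfg)
  expect_equal(tl$bce, log(2), tolerance = 1e-6)
  expect_equal(tl$ohem, log(2), tolerance = 1e-6)
  d <- diceLoss(segP4, segY4, eps = 1e-12)
  expect_equal(d, 1 / 3, tolerance = 1e-9)
  expect_equal(0.5 * log(2) + 0.3 * (1 / 3) + 0.2 * log(2), 0.5852,
               tolerance = 1e-3)
  combined <- w$alpha * tl$bce + w$beta * d + w$gamma * tl$ohem
  expect_equal(combined, 0.5852, tolerance = 1e-3)
  # zero components give zero; doubling gamma doubles the ohem share
  z <- totalLoss(segY, segY, segY, segY, weights = w,
                 cfg = lossConfig(diceEpsilon = 1))
  expect_lt(z$total, 1e-4)
  t1 <- totalLoss(segP, segY, segP, segY, weights = lossWeights(0, 0, 1), cfg = cfg)
  t2 <- totalLoss(segP, segY, segP, segY, weights = lossWeights(0, 0, 2), cfg = cfg)
  expect_equal(t2$total, 2 * t1$total, tolerance = 1e-12)
})

test_that("losses are nonnegative and finite even at extreme probabilities", {
  set.seed(56)
  p <- matrix(c(0, 1, runif(14)), 4, 4)
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  expect_true(is.finite(bceLoss(p, y)) && bceLoss(p, y) >= 0)
  expect_true(is.finite(diceLoss(p, y)) && diceLoss(p, y) >= 0)
  expect_true(is.finite(ohemBce(p, y)) && ohemBce(p, y) >= 0)
})

test_that("logit-space training losses agree with the probability-space definitions", {
  set.seed(57)
  z <- array(rnorm(64), c(4, 4, 1, 4))
  y <- (array(runif(64), c(4, 4, 1, 4)) > 0.6) * 1
  p <- 1 / (1 + exp(-z))
  expect_equal(axialseg:::agValue(axialseg:::agBceWithLogitsMean(axialseg:::agTensor(z), y)),
               bceLoss(p, y), tolerance = 1e-10)
  # per-sample dice averaged over the batch
  ref <- mean(vapply(1:4, function(n) diceLoss(p[, , 1, n], y[, , 1, n]), numeric(1)))
  expect_equal(axialseg:::agValue(axialseg:::agDiceWithLogitsMean(axialseg:::agTensor(z), y)),
               ref, tolerance = 1e-10)
  refOhem <- mean(vapply(1:4, function(n) {
    ohemBce(p[, , 1, n], y[, , 1, n], lossConfig(ohemKeepFraction = 0.5, ohemMinKept = 2L),
            clip = 0)
  }, numeric(1)))
  expect_equal(axialseg:::agValue(axialseg:::agOhemBceWithLogitsMean(
    axialseg:::agTensor(z), y, 0.5, 2L)), refOhem, tolerance = 1e-10)
})
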