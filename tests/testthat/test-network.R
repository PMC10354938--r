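# end-to-end network contracts: shapes at desk and full scale, encoder unit
# stride bookkeeping, bottleneck reduction, decoder chain, determinism, and
# gradient reachability of both encoder branches

test_that("desk-scale forward produces full-resolution seg and edge logits", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 101)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  out <- networkForward(x, net$params, cfg)
  expect_equal(dim(out$seg), c(64, 64, 1, 2))
  expect_equal(dim(out$edge), c(64, 64, 1, 2))
  expect_true(all(is.finite(out$seg)))
  expect_error(networkForward(array(0, c(32, 32, 3, 1)), net$params, cfg), "inputSize")
})

test_that("full-scale (512) configuration keeps the shape contract", {
  cfg <- networkConfig(inputSize = 512L, stemBase = 8L,
                       stageBlocks = c(1L, 1L, 1L, 1L),
                       embedDims = c(16L, 16L), unitDepth = 1L,
                       bottleneckDim = 32L, bottleneckDepth = 1L, heads = 2L,
                       decoderChannels = c(32L, 24L, 16L, 12L, 8L))
  net <- createNetwork(cfg, seed = 102)
  x <- array(runif(512 * 512 * 3), c(512, 512, 3, 1))
  out <- networkForward(x, net$params, cfg)
  expect_equal(dim(out$seg), c(512, 512, 1, 1))
})

test_that("edge head can be disabled or derived from the segmentation gradient", {
  cfg <- tinyNetworkConfig()
  cfg$edgeHead <- FALSE
  net <- createNetwork(cfg, seed = 103)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  expect_null(networkForward(x, net$params, cfg)$edge)
  cfg2 <- tinyNetworkConfig()
  cfg2$edgeFromGradient <- TRUE
  net2 <- createNetwork(cfg2, seed = 103)
  out2 <- networkForward(x, net2$params, cfg2)
  expect_equal(dim(out2$edge), c(64, 64, 1, 1))
  expect_true(all(is.finite(out2$edge)))
})

test_that("encoder units halve the extent and two stacked units quarter it", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 104)
  P <- axialseg:::wrapParamTree(net$params)
  x <- axialseg:::agTensor(array(rnorm(8 * 8 * 128 * 1), c(8, 8, 128, 1)))
  u1 <- axialseg:::agUnitForward(x, P$units[[1]], training = TRUE)
  expect_equal(dim(axialseg:::agValue(u1))[1:2], c(4, 4))
  u2 <- axialseg:::agUnitForward(u1, P$units[[2]], training = TRUE)
  expect_equal(dim(axialseg:::agValue(u2))[1:2], c(2, 2))
})

test_that("bottleneck preserves extent and reduces to the projection at depth 0", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 105)
  P <- axialseg:::wrapParamTree(net$params)
  x <- axialseg:::agTensor(array(rnorm(2 * 2 * 512), c(2, 2, 512, 1)))
  y <- axialseg:::agBottleneck(x, P$bottleneck, training = TRUE)
  expect_equal(dim(axialseg:::agValue(y)), c(2, 2, 128, 1))
  Pb0 <- P$bottleneck
  Pb0$blocks <- list()
  y0 <- axialseg:::agBottleneck(x, Pb0, training = TRUE)
  ref <- axialseg:::agConvBn(x, P$bottleneck$reduce, 1L, 0L, TRUE)
  expect_equal(axialseg:::agValue(y0), axialseg:::agValue(ref), tolerance = 1e-12)
})

test_that("evaluation-mode forward is deterministic and batch rows are independent", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 106)
  x <- array(runif(64 * 64 * 3 * 2), c(64, 64, 3, 2))
  o1 <- networkForward(x, net$params, cfg)
  o2 <- networkForward(x, net$params, cfg)
  expect_identical(o1$seg, o2$seg)
  x2 <- x
  x2[, , , 2] <- x[, , , 1]
  o3 <- networkForward(x2, net$params, cfg)
  expect_equal(o3$seg[, , , 1], o3$seg[, , , 2], tolerance = 1e-12)
})

test_that("a scalar loss reaches parameters of both encoder branches", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 107)
  P <- axialseg:::wrapParamTree(net$params, requires_grad = TRUE)
  x <- axialseg:::agTensor(array(runif(64 * 64 * 3), c(64, 64, 3, 1)))
  out <- axialseg:::agNetworkForward(x, P, cfg, training = TRUE)
  axialseg:::agBackward(axialseg:::agMean(axialseg:::agMul(out$seg, out$seg)))
  branchGrad <- function(p) {
    got <- FALSE
    axialseg:::walkAgLeaves(p, function(t, path) {
      if (!is.null(t$grad) && any(t$grad != 0)) got <<- TRUE
    })
    got
  }
  expect_true(branchGrad(P$units[[1]]$blocks))   # transformer branch
  expect_true(branchGrad(P$units[[1]]$stage))    # convolution branch
  expect_true(branchGrad(P$units[[2]]$blocks))
  expect_true(branchGrad(P$units[[2]]$stage))
})

test_that("zeroed segmentation head collapses logits to its bias", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 108)
  net$params$head$W <- 0 * net$params$head$W
  net$params$head$b <- 0.37
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  out <- networkForward(x, net$params, cfg)
  expect_equal(as.vector(out$seg), rep(0.37, 64 * 64), tolerance = 1e-12)
})

test_that("a desk-scale forward+backward pass fits the interactive budget", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 109)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  y <- (array(runif(64 * 64), c(64, 64, 1, 1)) > 0.7) * 1
  t0 <- Sys.time()
  P <- axialseg:::wrapParamTree(net$params, requires_grad = TRUE)
  out <- axialseg:::agNetworkForward(axialseg:::agTensor(x), P, cfg, training = TRUE)
  L <- axialseg:::agTotalLoss(out$seg, y, out$edge, y, lossWeights(), lossConfig())
  axialseg:::agBackward(L$loss)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 5)
})
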