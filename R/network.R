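#' @name network
#' @title U-shaped parallel CNN-transformer segmentation network
#' @description
#' Assembly of the full network: convolutional stem, two encoder units (a
#' masked-axial transformer branch in parallel with a residual convolution
#' stage, fused by GLF), a standard-transformer bottleneck, and a
#' convolution + bilinear-upsampling decoder with skip connections feeding a
#' sigmoid segmentation head and an auxiliary edge head.
NULL

#' Network configuration
#'
#' @param inputSize input extent in pixels (divisible by 32).
#' @param stemBase width of the stem convolution; residual stages use the
#'   standard widths `4, 8, 16, 32 x stemBase`.
#' @param stageBlocks residual block counts of the four stages.
#' @param embedDims transformer embed width per encoder unit.
#' @param unitDepth masked-axial transformer blocks per unit.
#' @param bottleneckDim channel width of the bottleneck transformer.
#' @param bottleneckDepth standard transformer blocks in the bottleneck.
#' @param heads attention heads (embed widths must be divisible by it).
#' @param mlpRatio transformer MLP hidden-width multiplier.
#' @param maskK,maskAFraction,clampMask distance-mask hyperparameters, see
#'   [buildDistanceMask()].
#' @param decoderChannels widths of the five decoder stages.
#' @param edgeHead attach the auxiliary edge head?
#' @param edgeFromGradient derive edge probabilities from the spatial
#'   gradient of the segmentation map instead of a dedicated head.
#' @export
networkConfig <- function(inputSize = 512L, stemBase = 64L,
                          stageBlocks = c(3L, 4L, 6L, 3L),
                          embedDims = c(256L, 256L), unitDepth = 2L,
                          bottleneckDim = 512L, bottleneckDepth = 4L,
                          heads = 8L, mlpRatio = 2,
                          maskK = 0.5, maskAFraction = 0.5, clampMask = FALSE,
                          decoderChannels = c(256L, 128L, 64L, 32L, 16L),
                          edgeHead = TRUE, edgeFromGradient = FALSE) {
  if (inputSize %% 32L != 0L) stop("inputSize must be divisible by 32")
  if (length(stageBlocks) != 4L) stop("stageBlocks must have length 4")
  if (length(embedDims) != 2L) stop("embedDims must have length 2 (two encoder units)")
  if (length(decoderChannels) != 5L) stop("decoderChannels must have length 5")
  structure(list(inputSize = as.integer(inputSize),
                 stemBase = as.integer(stemBase),
                 stageBlocks = as.integer(stageBlocks),
                 embedDims = as.integer(embedDims),
                 unitDepth = as.integer(unitDepth),
                 bottleneckDim = as.integer(bottleneckDim),
                 bottleneckDepth = as.integer(bottleneckDepth),
                 heads = as.integer(heads), mlpRatio = mlpRatio,
                 maskK = maskK, maskAFraction = maskAFraction,
                 clampMask = clampMask,
                 decoderChannels = as.integer(decoderChannels),
                 edgeHead = isTRUE(edgeHead),
                 edgeFromGradient = isTRUE(edgeFromGradient)),
            class = "networkConfig")
}

#' Desk-scale network configuration
#'
#' A 64x64, width-16 variant used throughout the test suite and the
#' synthetic-data experiments: the same architecture at reduced width and
#' depth so a forward/backward pass runs in seconds on one CPU core.
#' @param inputSize input extent (default 64).
#' @export
tinyNetworkConfig <- function(inputSize = 64L) {
  networkConfig(inputSize = inputSize, stemBase = 16L,
                stageBlocks = c(1L, 1L, 1L, 1L),
                embedDims = c(64L, 64L), unitDepth = 2L,
                bottleneckDim = 128L, bottleneckDepth = 4L,
                heads = 2L, mlpRatio = 2,
                decoderChannels = c(128L, 64L, 48L, 32L, 16L))
}

stageWidths <- function(cfg) cfg$stemBase * c(4L, 8L, 16L, 32L)

unitAttentionConfig <- function(cfg, i) {
  attentionConfig(embedDim = cfg$embedDims[i], heads = cfg$heads,
                  mlpRatio = cfg$mlpRatio, maskK = cfg$maskK,
                  maskAFraction = cfg$maskAFraction, clampMask = cfg$clampMask)
}

#' Initialize all network parameters
#'
#' @param cfg a [networkConfig()].
#' @return nested parameter tree (seed the RNG beforehand for
#'   reproducibility).
#' @export
initNetwork <- function(cfg) {
  sw <- stageWidths(cfg)
  unitIn <- c(sw[2], sw[3])     # features entering units 1 and 2
  unitOut <- c(sw[3], sw[4])    # GLF output widths (= CNN branch widths)
  units <- vector("list", 2L)
  for (i in 1:2) {
    acfg <- unitAttentionConfig(cfg, i)
    blocks <- lapply(seq_len(cfg$unitDepth), function(j) initAttentionParams(acfg))
    units[[i]] <- list(
      proj = initConvBn(1L, 1L, unitIn[i], cfg$embedDims[i]),
      blocks = blocks,
      stage = initResStage(resStageConfig(unitIn[i], unitOut[i],
                                          cfg$stageBlocks[2L + i], 2L)),
      glf = initGlf(cfg$embedDims[i], unitOut[i], unitOut[i]),
      acfg = acfg
    )
  }
  bcfg <- attentionConfig(embedDim = cfg$bottleneckDim, heads = cfg$heads,
                          mlpRatio = cfg$mlpRatio)
  bottleneck <- list(
    reduce = initConvBn(1L, 1L, unitOut[2], cfg$bottleneckDim),
    blocks = lapply(seq_len(cfg$bottleneckDepth), function(j) initAttentionParams(bcfg)),
    acfg = bcfg
  )
  skipCh <- c(unitOut[1], sw[2], sw[1], cfg$stemBase)  # deep -> shallow
  dc <- cfg$decoderChannels
  inCh <- cfg$bottleneckDim
  dec <- vector("list", 5L)
  for (s in 1:5) {
    catCh <- inCh + if (s <= 4L) skipCh[s] else 0L
    dec[[s]] <- list(
      conv1 = initConvBn(3L, 3L, catCh, dc[s]),
      conv2 = initConvBn(3L, 3L, dc[s], dc[s])
    )
    inCh <- dc[s]
  }
  head <- list(W = heConv(1L, 1L, dc[5], 1L), b = numeric(1))
  p <- list(stem = initStem(cfg$stemBase, cfg$stageBlocks[1], cfg$stageBlocks[2]),
            units = units, bottleneck = bottleneck, decoder = dec, head = head)
  if (cfg$edgeHead && !cfg$edgeFromGradient) {
    p$edgeHead <- list(W = heConv(1L, 1L, dc[5], 1L), b = numeric(1))
  }
  p
}

# one encoder unit: parallel transformer branch (avgpool tokens, 1x1
# projection, masked-axial blocks) and residual stage branch, fused by GLF
agUnitForward <- function(x, P, training) {
  tokens <- agConvBn(agAvgPool2(x), P$proj, stride = 1L, pad = 0L,
                     training = training)
  for (blk in P$blocks) {
    tokens <- agTransformerBlock(tokens, P$acfg, blk, kind = "masked_axial")
  }
  local <- agResStage(x, P$stage, training)
  dg <- dim(agValue(tokens)); dl <- dim(agValue(local))
  if (!all(dg[c(1, 2)] == dl[c(1, 2)])) {
    stop("encoder unit branches produced mismatched spatial extents")
  }
  agGlfFuse(tokens, local, P$glf, training = training)
}

agBottleneck <- function(x, P, training) {
  y <- agConvBn(x, P$reduce, stride = 1L, pad = 0L, training = training)
  for (blk in P$blocks) {
    y <- agTransformerBlock(y, P$acfg, blk, kind = "standard")
  }
  y
}

agDecoder <- function(deep, skips, P, cfg, training) {
  # skips ordered deep -> shallow: unit1, stage2, stage1, stem conv
  y <- deep
  for (s in 1:5) {
    y <- agUpsample2(y)
    if (s <= 4L) {
      sk <- skips[[s]]
      dy <- dim(agValue(y)); ds <- dim(agValue(sk))
      if (!all(dy[c(1, 2)] == ds[c(1, 2)])) {
        stop("skip connection extent does not match decoder stage")
      }
      y <- agConcatC(y, sk)
    }
    y <- agConvBn(y, P[[s]]$conv1, stride = 1L, pad = 1L, training = training)
    y <- agConvBn(y, P[[s]]$conv2, stride = 1L, pad = 1L, training = training)
  }
  y
}

agNetworkForward <- function(x, P, cfg, training = FALSE) {
  d <- dim(agValue(x))
  if (d[1] != cfg$inputSize || d[2] != cfg$inputSize) {
    stop("input extent does not match cfg$inputSize")
  }
  st <- agStem(x, P$stem, training)
  u1 <- agUnitForward(st$features, P$units[[1]], training)
  u2 <- agUnitForward(u1, P$units[[2]], training)
  bn <- agBottleneck(u2, P$bottleneck, training)
  feat <- agDecoder(bn, list(u1, st$skips[[3]], st$skips[[2]], st$skips[[1]]),
                    P$decoder, cfg, training)
  seg <- agConv2d(feat, P$head$W, P$head$b, stride = 1L, pad = 0L)
  edge <- NULL
  if (cfg$edgeHead) {
    if (cfg$edgeFromGradient) {
      edge <- agSpatialGradientMagnitude(seg)
    } else {
      edge <- agConv2d(feat, P$edgeHead$W, P$edgeHead$b, stride = 1L, pad = 0L)
    }
  }
  list(seg = seg, edge = edge)
}

# edge logits from the spatial gradient of the segmentation probability
# (config alternative to the dedicated edge head): logit of |grad sigmoid|
agSpatialGradientMagnitude <- function(seg) {
  p <- agSigmoid(seg)
  d <- dim(agValue(p))
  H <- d[1]; W <- d[2]
  shiftH <- function(t) {
    v <- agValue(t)
    vs <- v[c(2:H, H), , , , drop = FALSE]
    agOp(vs, list(t), function(g) {
      gx <- array(0, d)
      gx[2:H, , , ] <- g[seq_len(H - 1L), , , , drop = FALSE]
      gx[H, , , ] <- gx[H, , , , drop = FALSE] + g[H, , , , drop = FALSE]
      list(gx)
    })
  }
  shiftW <- function(t) {
    v <- agValue(t)
    vs <- v[, c(2:W, W), , , drop = FALSE]
    agOp(vs, list(t), function(g) {
      gx <- array(0, d)
      gx[, 2:W, , ] <- g[, seq_len(W - 1L), , , drop = FALSE]
      gx[, W, , ] <- gx[, W, , , drop = FALSE] + g[, W, , , drop = FALSE]
      list(gx)
    })
  }
  dh <- agAdd(shiftH(p), agScale(p, -1))
  dw <- agAdd(shiftW(p), agScale(p, -1))
  mag <- agAdd(agMul(dh, dh), agMul(dw, dw))
  # map squared gradient in [0, 2] to a logit scale
  agAddScalar(agScale(mag, 8), -4)
}

#' Full network forward pass
#'
#' @param x image batch `[H, W, 3, N]` with `H = W = cfg$inputSize`.
#' @param params parameter tree from [initNetwork()].
#' @param cfg the matching [networkConfig()].
#' @param training batch-norm mode (`FALSE` = deterministic evaluation).
#' @return list with `seg` (`[H, W, 1, N]` segmentation logits) and `edge`
#'   (edge logits, or `NULL` when the edge head is disabled).
#' @export
networkForward <- function(x, params, cfg, training = FALSE) {
  out <- agNetworkForward(agTensor(x), wrapParamTree(params), cfg,
                          training = training)
  list(seg = agValue(out$seg),
       edge = if (is.null(out$edge)) NULL else agValue(out$edge))
}
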