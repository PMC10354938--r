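#' @name fusion
#' @title Global-local fusing (GLF)
#' @description
#' Attention-gated fusion of the transformer (global) and convolution
#' (local) encoder streams. The global stream produces a spatial gate (from
#' channel-axis mean/max pooling and a 7x7 convolution) and a channel gate
#' (from global average pooling and a two-layer bottleneck fully-connected
#' map); both gates multiply the local stream, each stream is compressed by
#' a 1x1 convolution, the streams are concatenated on the channel axis, and
#' a final 3x3 convolution produces the fused output.
NULL

#' Initialize a GLF module
#'
#' @param cGlobal channels of the transformer-branch input.
#' @param cLocal channels of the convolution-branch input.
#' @param cOut fused output channels (each compressed stream gets `cOut/2`).
#' @param reduction bottleneck reduction of the channel-gate MLP.
#' @param kSpatial spatial-gate convolution size (odd).
#' @export
initGlf <- function(cGlobal, cLocal, cOut, reduction = 4L, kSpatial = 7L) {
  hidden <- max(1L, cGlobal %/% reduction)
  half <- max(1L, cOut %/% 2L)
  list(
    saW = heConv(kSpatial, kSpatial, 2L, 1L), saB = numeric(1),
    caW1 = matrix(stats::rnorm(cGlobal * hidden, sd = 1 / sqrt(cGlobal)), cGlobal, hidden),
    caB1 = numeric(hidden),
    caW2 = matrix(stats::rnorm(hidden * cLocal, sd = 1 / sqrt(hidden)), hidden, cLocal),
    caB2 = numeric(cLocal),
    compG = initConvBn(1L, 1L, cGlobal, half),
    compL = initConvBn(1L, 1L, cLocal, half),
    fuse = initConvBn(3L, 3L, 2L * half, cOut),
    kPad = (kSpatial - 1L) %/% 2L
  )
}

agSpatialGate <- function(fg, P) {
  mm <- agChannelMeanMax(fg)
  z <- agConv2d(mm, P$saW, P$saB, stride = 1L, pad = P$kPad)
  agSigmoid(z)
}

agChannelGate <- function(fg, P) {
  g <- agGlobalAvgPool(fg)                      # [Cg, N]
  g <- agAperm(g, c(2, 1))                      # [N, Cg]
  g <- agRelu(agLinear(g, P$caW1, P$caB1))
  g <- agSigmoid(agLinear(g, P$caW2, P$caB2))   # [N, Clocal]
  agAperm(g, c(2, 1))                           # [Clocal, N]
}

agGlfFuse <- function(fg, fl, P, training,
                      forceSpatial = NULL, forceChannel = NULL) {
  dg <- dim(agValue(fg)); dl <- dim(agValue(fl))
  if (!all(dg[c(1, 2, 4)] == dl[c(1, 2, 4)])) {
    stop("global and local streams disagree in spatial extent or batch")
  }
  As <- if (is.null(forceSpatial)) agSpatialGate(fg, P) else
    agTensor(array(forceSpatial, c(dg[1], dg[2], 1L, dg[4])))
  Ac <- if (is.null(forceChannel)) agChannelGate(fg, P) else
    agTensor(matrix(forceChannel, dl[3], dl[4]))
  gated <- agMulChannelGate(agMulSpatialGate(fl, As), Ac)
  cg <- agConvBn(fg, P$compG, stride = 1L, pad = 0L, training = training)
  cl <- agConvBn(gated, P$compL, stride = 1L, pad = 0L, training = training)
  agConvBn(agConcatC(cg, cl), P$fuse, stride = 1L, pad = 1L, training = training)
}

#' Spatial attention gate of the GLF module
#'
#' Channel-axis mean and max pooling of the global features, a 7x7
#' convolution and a sigmoid: one gate value per spatial position.
#'
#' @param fGlobal `[H, W, C, N]` transformer-branch features.
#' @param params parameters from [initGlf()].
#' @return `[H, W, 1, N]` array with entries in (0, 1).
#' @export
spatialAttention <- function(fGlobal, params) {
  agValue(agSpatialGate(agTensor(fGlobal), wrapParamTree(params)))
}

#' Channel attention gate of the GLF module
#'
#' Global spatial average pooling of the global features followed by a
#' two-layer bottleneck fully-connected map and a sigmoid: one gate per
#' local-stream channel.
#'
#' @inheritParams spatialAttention
#' @return `[C_local, N]` matrix with entries in (0, 1).
#' @export
channelAttention <- function(fGlobal, params) {
  agValue(agChannelGate(agTensor(fGlobal), wrapParamTree(params)))
}

#' Fuse global and local encoder streams
#'
#' The local stream is gated elementwise by the spatial gate (broadcast over
#' channels) and the channel gate (broadcast over space); each stream passes
#' a channel-compressing 1x1 convolution, the streams are concatenated and a
#' final 3x3 convolution produces the output at the configured width.
#'
#' @param fGlobal,fLocal `[H, W, C, N]` feature pair with matching spatial
#'   extent and batch.
#' @param params parameters from [initGlf()].
#' @param training batch-norm mode.
#' @param forceSpatial,forceChannel test hooks: constants overriding the
#'   gates (e.g. 1 for identity gating), or `NULL` to compute them.
#' @return fused `[H, W, cOut, N]` feature map.
#' @export
glfFuse <- function(fGlobal, fLocal, params, training = FALSE,
                    forceSpatial = NULL, forceChannel = NULL) {
  agValue(agGlfFuse(agTensor(fGlobal), agTensor(fLocal), wrapParamTree(params),
                    training = training, forceSpatial = forceSpatial,
                    forceChannel = forceChannel))
}
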