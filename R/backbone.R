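#' @name backbone
#' @title Residual convolution stem and stages
#' @description
#' The local (convolutional) branch of the encoder: a five-stage bottleneck
#' residual backbone in the classic 50-layer layout. The stem (7x7 stride-2
#' convolution, 3x3 stride-2 max pool, stages 1-2) aggregates low-level
#' features and records every intermediate scale for the decoder's skip
#' connections; stages 3-4 serve as the convolution branches of the two
#' encoder units.
NULL

heConv <- function(kh, kw, cin, cout) {
  array(stats::rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}

initBnState <- function(C) {
  e <- new.env(parent = emptyenv())
  e$running_mean <- numeric(C)
  e$running_var <- rep(1, C)
  e
}

initBn <- function(C) list(gamma = rep(1, C), beta = numeric(C), state = initBnState(C))

initConvBn <- function(kh, kw, cin, cout) {
  list(W = heConv(kh, kw, cin, cout), bn = initBn(cout))
}

agConvBn <- function(x, P, stride, pad, training, relu = TRUE) {
  y <- agConv2d(x, P$W, NULL, stride = stride, pad = pad)
  y <- agBatchNorm(y, P$bn$gamma, P$bn$beta, P$bn$state, training = training)
  if (relu) agRelu(y) else y
}

#' Residual stage configuration
#'
#' @param inChannels,outChannels channel widths entering and leaving the stage.
#' @param blocks number of bottleneck residual blocks (>= 1).
#' @param stride entry stride, 1 or 2.
#' @param expansion bottleneck expansion factor (mid width = out/expansion).
#' @export
resStageConfig <- function(inChannels, outChannels, blocks = 1L, stride = 1L,
                           expansion = 4L) {
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  if (blocks < 1L) stop("blocks must be >= 1")
  structure(list(inChannels = as.integer(inChannels),
                 outChannels = as.integer(outChannels),
                 blocks = as.integer(blocks), stride = as.integer(stride),
                 expansion = as.integer(expansion)),
            class = "resStageConfig")
}

#' Initialize a bottleneck residual stage
#' @param cfg a [resStageConfig()].
#' @return nested parameter list (arrays + batch-norm state).
#' @export
initResStage <- function(cfg) {
  mid <- max(1L, cfg$outChannels %/% cfg$expansion)
  blocks <- vector("list", cfg$blocks)
  for (b in seq_len(cfg$blocks)) {
    cin <- if (b == 1L) cfg$inChannels else cfg$outChannels
    s <- if (b == 1L) cfg$stride else 1L
    blk <- list(
      c1 = initConvBn(1L, 1L, cin, mid),
      c2 = initConvBn(3L, 3L, mid, mid),
      c3 = initConvBn(1L, 1L, mid, cfg$outChannels),
      stride = s
    )
    if (s != 1L || cin != cfg$outChannels) {
      blk$proj <- initConvBn(1L, 1L, cin, cfg$outChannels)
    }
    blocks[[b]] <- blk
  }
  list(blocks = blocks, cfg = cfg)
}

agResBlock <- function(x, P, training) {
  identity <- if (!is.null(P$proj)) {
    agConvBn(x, P$proj, stride = P$stride, pad = 0L, training = training, relu = FALSE)
  } else x
  y <- agConvBn(x, P$c1, stride = 1L, pad = 0L, training = training)
  y <- agConvBn(y, P$c2, stride = P$stride, pad = 1L, training = training)
  y <- agConvBn(y, P$c3, stride = 1L, pad = 0L, training = training, relu = FALSE)
  agRelu(agAdd(identity, y))
}

agResStage <- function(x, P, training) {
  for (blk in P$blocks) x <- agResBlock(x, blk, training)
  x
}

#' Run one residual stage on a feature map
#'
#' @param x `[H, W, C, N]` feature map with `C == cfg$inChannels`.
#' @param params parameters from [initResStage()].
#' @param training use batch statistics (TRUE) or running statistics.
#' @return feature map `[H/stride, W/stride, outChannels, N]`.
#' @export
resStageForward <- function(x, params, training = FALSE) {
  if (dim(x)[3] != params$cfg$inChannels) {
    stop("input channels do not match stage configuration")
  }
  agValue(agResStage(agTensor(x), wrapParamTree(params), training))
}

#' Initialize the convolutional stem
#'
#' 7x7 stride-2 convolution, 3x3 stride-2 max pool, then residual stages 1
#' (stride 1) and 2 (stride 2): input `H` maps to `H/8` at the deepest stem
#' output.
#'
#' @param base width of the first convolution; stages 1-2 use the standard
#'   widths `4*base` and `8*base`.
#' @param blocks1,blocks2 residual block counts of stages 1 and 2.
#' @param inChannels image channels (3 for RGB).
#' @export
initStem <- function(base = 64L, blocks1 = 1L, blocks2 = 1L, inChannels = 3L) {
  list(
    conv1 = initConvBn(7L, 7L, inChannels, base),
    stage1 = initResStage(resStageConfig(base, 4L * base, blocks1, 1L)),
    stage2 = initResStage(resStageConfig(4L * base, 8L * base, blocks2, 2L)),
    base = base
  )
}

agStem <- function(x, P, training) {
  d <- dim(agValue(x))
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop("stem input extent must be divisible by 16")
  }
  c1 <- agConvBn(x, P$conv1, stride = 2L, pad = 3L, training = training)
  p1 <- agMaxPool3s2(c1)
  s1 <- agResStage(p1, P$stage1, training)
  s2 <- agResStage(s1, P$stage2, training)
  list(features = s2, skips = list(c1, s1, s2))
}

#' Run the stem on an image batch
#'
#' @param x image batch `[H, W, 3, N]`, `H`, `W` divisible by 16.
#' @param params parameters from [initStem()].
#' @param training batch-norm mode.
#' @return list with `features` (deepest output, `H/8 x W/8`) and `skips`
#'   (post-convolution at `H/2`, post-stage-1 at `H/4`, post-stage-2 at
#'   `H/8`).
#' @export
stemForward <- function(x, params, training = FALSE) {
  out <- agStem(agTensor(x), wrapParamTree(params), training)
  list(features = agValue(out$features), skips = lapply(out$skips, agValue))
}
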