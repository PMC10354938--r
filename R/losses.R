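#' @name losses
#' @title Composite training objective
#' @description
#' Binary cross-entropy and soft Dice loss on the segmentation map, a
#' Canny-derived edge ground truth, an online hard-example-mining (Ohem)
#' BCE on the edge map, and the weighted total
#' `alpha * L_BCE + beta * L_Dice + gamma * L_Ohem` with default weights
#' 0.5 / 0.3 / 0.2.
NULL

#' Loss weights
#' @param alpha,beta,gamma nonnegative weights of the BCE, Dice and Ohem
#'   terms (defaults 0.5, 0.3, 0.2).
#' @export
lossWeights <- function(alpha = 0.5, beta = 0.3, gamma = 0.2) {
  w <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(w)) || any(w < 0)) stop("weights must be finite and nonnegative")
  as.list(w)
}

#' Loss configuration
#'
#' @param diceEpsilon smoothing constant of the Dice loss.
#' @param diceFactorTwo keep the conventional factor 2 in the Dice numerator
#'   so a perfect prediction attains loss 0 (`FALSE` reproduces the raw
#'   printed form, whose optimum is 0.5).
#' @param ohemKeepFraction fraction of pixels kept by the Ohem loss.
#' @param ohemMinKept minimum number of pixels kept per image.
#' @param cannyLow,cannyHigh hysteresis thresholds on the 0-255 gradient
#'   scale ("a large threshold range": 10 / 100).
#' @param edgeDilation pixels of edge-band thickening so the supervision is
#'   not a one-pixel hairline.
#' @param reduction `"mean"` (batch-size independent) or `"sum"`.
#' @export
lossConfig <- function(diceEpsilon = 1.0, diceFactorTwo = TRUE,
                       ohemKeepFraction = 0.25, ohemMinKept = 256L,
                       cannyLow = 10, cannyHigh = 100,
                       edgeDilation = 1L, reduction = c("mean", "sum")) {
  if (ohemKeepFraction <= 0 || ohemKeepFraction > 1) {
    stop("ohemKeepFraction must be in (0, 1]")
  }
  if (cannyLow >= cannyHigh) stop("cannyLow must be below cannyHigh")
  structure(list(diceEpsilon = diceEpsilon, diceFactorTwo = diceFactorTwo,
                 ohemKeepFraction = ohemKeepFraction,
                 ohemMinKept = as.integer(ohemMinKept),
                 cannyLow = cannyLow, cannyHigh = cannyHigh,
                 edgeDilation = as.integer(edgeDilation),
                 reduction = match.arg(reduction)),
            class = "lossConfig")
}

#' Binary cross-entropy loss
#'
#' Mean over pixels of `-(y log p + (1 - y) log(1 - p))`; probabilities are
#' clipped away from 0 and 1.
#'
#' @param p probability map in `[0, 1]`.
#' @param y binary ground-truth map of the same shape.
#' @param reduction `"mean"` or `"sum"`.
#' @param clip probability floor/ceiling.
#' @export
bceLoss <- function(p, y, reduction = c("mean", "sum"), clip = 1e-7) {
  reduction <- match.arg(reduction)
  if (length(p) != length(y)) stop("shape mismatch between p and y")
  pc <- pmin(pmax(p, clip), 1 - clip)
  l <- -(y * log(pc) + (1 - y) * log(1 - pc))
  if (reduction == "mean") mean(l) else sum(l)
}

#' Soft Dice loss
#'
#' `1 - (2 sum(y p) + eps) / (sum(y) + sum(p) + eps)` (the factor 2 can be
#' dropped with `factorTwo = FALSE`, reproducing the raw form whose optimum
#' is 0.5 instead of 0).
#'
#' @inheritParams bceLoss
#' @param eps smoothing constant (> 0).
#' @param factorTwo keep the conventional factor 2 in the numerator.
#' @export
diceLoss <- function(p, y, eps = 1.0, factorTwo = TRUE) {
  if (length(p) != length(y)) stop("shape mismatch between p and y")
  if (eps <= 0) stop("eps must be positive")
  fac <- if (factorTwo) 2 else 1
  1 - (fac * sum(p * y) + eps) / (sum(p) + sum(y) + eps)
}

## ---- small image helpers (plain, non-differentiable) ---------------------

gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable convolution of a matrix with replicated borders
blurMatrix <- function(m, sigma) {
  k <- gaussianKernel1d(sigma)
  if (length(k) == 1L) return(m)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  rows <- pmin(pmax(outer(seq_len(H), -r:r, "+"), 1L), H)
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * m[rows[, i], , drop = FALSE]
  m <- out
  cols <- pmin(pmax(outer(seq_len(W), -r:r, "+"), 1L), W)
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * m[, cols[, i], drop = FALSE]
  out
}

shiftMatrix <- function(m, di, dj, fill = 0, replicate = FALSE) {
  H <- nrow(m); W <- ncol(m)
  si <- seq_len(H) + di
  sj <- seq_len(W) + dj
  if (replicate) {
    return(m[pmin(pmax(si, 1L), H), pmin(pmax(sj, 1L), W), drop = FALSE])
  }
  out <- matrix(fill, H, W)
  ok_i <- si >= 1L & si <= H
  ok_j <- sj >= 1L & sj <= W
  out[ok_i, ok_j] <- m[si[ok_i], sj[ok_j]]
  out
}

dilateBinary <- function(m, iter = 1L) {
  for (it in seq_len(iter)) {
    acc <- m
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      acc <- pmax(acc, shiftMatrix(m, di, dj))
    }
    m <- acc
  }
  m
}

#' Canny edge mask of a binary segmentation mask
#'
#' Classical Canny on the mask scaled to 0-255: Gaussian smoothing, Sobel
#' gradients, non-maximum suppression along the quantized gradient
#' direction, double thresholding and hysteresis (weak edges survive only
#' when connected to a strong edge), then optional dilation of the edge
#' band.
#'
#' @param mask binary matrix (values 0/1).
#' @param cfg a [lossConfig()] carrying the hysteresis thresholds and the
#'   dilation radius.
#' @param sigma Gaussian smoothing in pixels.
#' @return binary matrix of edge pixels.
#' @export
cannyEdgeMask <- function(mask, cfg = lossConfig(), sigma = 1) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  m <- blurMatrix(mask * 255, sigma)
  # Sobel with replicated borders (row axis = i/H, col axis = j/W)
  sh <- function(di, dj) shiftMatrix(m, di, dj, replicate = TRUE)
  gi <- sh(1, 0) - sh(-1, 0)
  gj <- sh(0, 1) - sh(0, -1)
  gi2 <- gi + 0.5 * (sh(1, 1) - sh(-1, 1) + sh(1, -1) - sh(-1, -1))
  gj2 <- gj + 0.5 * (sh(1, 1) - sh(1, -1) + sh(-1, 1) - sh(-1, -1))
  mag <- sqrt(gi2^2 + gj2^2) / 2
  if (all(mag == 0)) return(matrix(0, nrow(mask), ncol(mask)))
  ang <- atan2(gi2, gj2)
  # quantize direction to 0, 45, 90, 135 degrees
  sector <- (round(ang / (pi / 4)) %% 4)
  n1 <- matrix(0, nrow(mask), ncol(mask))
  n2 <- n1
  for (s in 0:3) {
    off <- switch(as.character(s),
                  "0" = c(0, 1), "1" = c(1, 1), "2" = c(1, 0), "3" = c(1, -1))
    sel <- sector == s
    n1[sel] <- shiftMatrix(mag, off[1], off[2])[sel]
    n2[sel] <- shiftMatrix(mag, -off[1], -off[2])[sel]
  }
  nms <- mag
  nms[mag < n1 | mag < n2] <- 0
  strong <- nms >= cfg$cannyHigh
  weak <- nms >= cfg$cannyLow
  # hysteresis: grow strong edges through weak ones to a fixed point
  cur <- strong
  repeat {
    grown <- dilateBinary(cur * 1, 1L) * weak
    if (all(grown == cur)) break
    cur <- grown
  }
  edge <- cur * 1
  if (cfg$edgeDilation > 0L) edge <- dilateBinary(edge, cfg$edgeDilation)
  edge
}

#' Online hard-example-mining BCE
#'
#' Per-pixel BCE is computed, pixels are sorted by loss (descending, ties
#' broken by pixel index so the result is deterministic), and the mean over
#' the top `max(ohemMinKept, ceiling(ohemKeepFraction * n))` pixels is
#' returned.
#'
#' @param p probability map.
#' @param y binary ground-truth map of the same shape.
#' @param cfg a [lossConfig()].
#' @param clip probability floor/ceiling.
#' @export
ohemBce <- function(p, y, cfg = lossConfig(), clip = 1e-7) {
  if (length(p) != length(y)) stop("shape mismatch between p and y")
  n <- length(p)
  if (n == 0L) stop("empty input")
  pc <- pmin(pmax(as.vector(p), clip), 1 - clip)
  l <- -(as.vector(y) * log(pc) + (1 - as.vector(y)) * log(1 - pc))
  keep <- max(cfg$ohemMinKept, as.integer(ceiling(cfg$ohemKeepFraction * n)))
  keep <- min(keep, n)
  ord <- order(-l, seq_len(n))
  mean(l[ord[seq_len(keep)]])
}

#' Weighted composite loss
#'
#' `alpha * BCE(segP, segY) + beta * Dice(segP, segY) +
#'  gamma * Ohem(edgeP, edgeY)`, with the three component values reported
#' alongside the total.
#'
#' @param segP,segY segmentation probability map and binary ground truth.
#' @param edgeP,edgeY edge probability map and binary edge ground truth
#'   (ignored with a zero Ohem term when `NULL`).
#' @param weights a [lossWeights()].
#' @param cfg a [lossConfig()].
#' @return list with `total`, `bce`, `dice`, `ohem`.
#' @export
totalLoss <- function(segP, segY, edgeP = NULL, edgeY = NULL,
                      weights = lossWeights(), cfg = lossConfig()) {
  b <- bceLoss(segP, segY, reduction = cfg$reduction)
  d <- diceLoss(segP, segY, eps = cfg$diceEpsilon, factorTwo = cfg$diceFactorTwo)
  o <- if (is.null(edgeP) || is.null(edgeY)) 0 else ohemBce(edgeP, edgeY, cfg)
  list(total = weights$alpha * b + weights$beta * d + weights$gamma * o,
       bce = b, dice = d, ohem = o)
}

# differentiable composite loss on logits (training path); returns the ag
# scalar plus detached component values
agTotalLoss <- function(segZ, segY, edgeZ, edgeY, weights, cfg) {
  b <- agBceWithLogitsMean(segZ, segY)
  d <- agDiceWithLogitsMean(segZ, segY, eps = cfg$diceEpsilon,
                            factorTwo = cfg$diceFactorTwo)
  total <- agAdd(agScale(b, weights$alpha), agScale(d, weights$beta))
  ov <- 0
  if (!is.null(edgeZ) && weights$gamma > 0) {
    o <- agOhemBceWithLogitsMean(edgeZ, edgeY,
                                 keepFraction = cfg$ohemKeepFraction,
                                 minKept = cfg$ohemMinKept)
    total <- agAdd(total, agScale(o, weights$gamma))
    ov <- agValue(o)
  }
  list(loss = total, bce = agValue(b), dice = agValue(d), ohem = ov)
}
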