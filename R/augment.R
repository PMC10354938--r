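#' @name augment
#' @title Data augmentation suite
#' @description
#' The training-time augmentation pipeline: random rotation, horizontal and
#' vertical flips, random crop-and-resize, and random elastic deformation
#' applied identically to image, mask and edge (nearest-neighbour
#' interpolation for the binary maps); then exactly one occlusion transform
#' (cutout, coarse dropout, grid distortion or grid dropout) applied to the
#' image only, so the supervision stays truthful.
NULL

# sample a matrix at fractional coordinates, clamped to the border
sampleMatrix <- function(m, mi, mj, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- nrow(m); W <- ncol(m)
  if (method == "nearest") {
    i <- pmin(pmax(round(mi), 1), H)
    j <- pmin(pmax(round(mj), 1), W)
    return(matrix(m[cbind(as.vector(i), as.vector(j))], nrow(mi), ncol(mi)))
  }
  i0 <- pmin(pmax(floor(mi), 1), H)
  j0 <- pmin(pmax(floor(mj), 1), W)
  i1 <- pmin(i0 + 1, H)
  j1 <- pmin(j0 + 1, W)
  fi <- pmin(pmax(mi - i0, 0), 1)
  fj <- pmin(pmax(mj - j0, 0), 1)
  g <- function(ii, jj) matrix(m[cbind(as.vector(ii), as.vector(jj))], nrow(mi), ncol(mi))
  (1 - fi) * ((1 - fj) * g(i0, j0) + fj * g(i0, j1)) +
    fi * ((1 - fj) * g(i1, j0) + fj * g(i1, j1))
}

#' Warp a sample through a coordinate map
#'
#' @param sample a `segSample`.
#' @param mi,mj source-coordinate matrices (same extent as the sample):
#'   output pixel `(i, j)` is sampled at `(mi[i,j], mj[i,j])`.
#' @return warped `segSample`; the image is interpolated bilinearly, mask
#'   and edge with nearest neighbour (staying binary).
#' @export
warpSample <- function(sample, mi, mj) {
  img <- sample$image
  for (c in seq_len(dim(img)[3])) {
    img[, , c] <- sampleMatrix(sample$image[, , c], mi, mj, "bilinear")
  }
  out <- sample
  out$image <- img
  out$mask <- sampleMatrix(sample$mask, mi, mj, "nearest")
  if (!is.null(sample$edge)) out$edge <- sampleMatrix(sample$edge, mi, mj, "nearest")
  out
}

#' Flip a sample
#' @param sample a `segSample`.
#' @param axis `"horizontal"` (left-right) or `"vertical"` (up-down).
#' @export
flipSample <- function(sample, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  fl <- function(m) if (axis == "horizontal") m[, rev(seq_len(ncol(m))), drop = FALSE]
                    else m[rev(seq_len(nrow(m))), , drop = FALSE]
  out <- sample
  for (c in seq_len(dim(sample$image)[3])) out$image[, , c] <- fl(sample$image[, , c])
  out$mask <- fl(sample$mask)
  if (!is.null(sample$edge)) out$edge <- fl(sample$edge)
  out
}

identityMap <- function(S) {
  list(mi = matrix(seq_len(S), S, S), mj = matrix(seq_len(S), S, S, byrow = TRUE))
}

## ---- occlusions (image only) ---------------------------------------------

occludeBox <- function(img, i0, j0, h, w, fill = 0) {
  S1 <- dim(img)[1]; S2 <- dim(img)[2]
  ii <- max(1, i0):min(S1, i0 + h - 1)
  jj <- max(1, j0):min(S2, j0 + w - 1)
  img[ii, jj, ] <- fill
  img
}

occlusionCutout <- function(img) {
  S <- dim(img)[1]
  sz <- ceiling(stats::runif(1, 0.15, 0.35) * S)
  occludeBox(img, sample.int(S - sz + 1, 1), sample.int(S - sz + 1, 1), sz, sz,
             fill = mean(img))
}

occlusionCoarseDropout <- function(img) {
  S <- dim(img)[1]
  nb <- sample(4:8, 1)
  sz <- max(2L, ceiling(0.08 * S))
  for (b in seq_len(nb)) {
    img <- occludeBox(img, sample.int(S - sz + 1, 1), sample.int(S - sz + 1, 1),
                      sz, sz, fill = 0)
  }
  img
}

occlusionGridDropout <- function(img) {
  S <- dim(img)[1]
  unit <- max(4L, S %/% 8L)
  hole <- max(1L, ceiling(0.4 * unit))
  off <- sample.int(unit, 2, replace = TRUE)
  for (i0 in seq(off[1], S, by = unit)) {
    for (j0 in seq(off[2], S, by = unit)) {
      img <- occludeBox(img, i0, j0, hole, hole, fill = 0)
    }
  }
  img
}

# grid distortion applied to the image intensities only: each cell of a
# 4x4 grid is resampled with a jittered corner lattice
occlusionGridDistort <- function(img) {
  S <- dim(img)[1]
  ncell <- 4L
  limit <- 0.15
  knots <- seq(0, S, length.out = ncell + 1)
  jitter <- function() {
    steps <- diff(knots) * (1 + stats::runif(ncell, -limit, limit))
    k <- cumsum(c(0, steps))
    k * (S / k[ncell + 1])
  }
  ki <- jitter(); kj <- jitter()
  mapAxis <- function(k) {
    out <- numeric(S)
    for (c in seq_len(ncell)) {
      lo <- floor(k[c]) + 1
      hi <- floor(k[c + 1])
      if (c == ncell) hi <- S
      idx <- lo:hi
      out[idx] <- knots[c] + (idx - k[c]) / (k[c + 1] - k[c]) * (knots[c + 1] - knots[c])
    }
    pmin(pmax(out, 1), S)
  }
  mi <- matrix(mapAxis(ki), S, S)
  mj <- matrix(mapAxis(kj), S, S, byrow = TRUE)
  for (c in seq_len(dim(img)[3])) {
    img[, , c] <- sampleMatrix(img[, , c], mi, mj, "bilinear")
  }
  img
}

#' Randomly augment a sample
#'
#' Applies, each with probability 1/2 and with all geometric maps composed
#' into a single resampling pass: rotation (up to +/- 30 degrees),
#' horizontal and vertical flips, crop-and-resize (scale 0.7-1) and elastic
#' deformation; then exactly one occlusion transform on the image only.
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param sample a `segSample`.
#' @param rotationLimit maximum absolute rotation in degrees.
#' @param elasticAlpha displacement amplitude of the elastic field, pixels.
#' @param elasticSigma smoothing of the elastic field, pixels.
#' @return augmented `segSample` (mask and edge stay binary).
#' @export
augmentSample <- function(sample, rotationLimit = 30,
                          elasticAlpha = 2.5, elasticSigma = 6) {
  S <- nrow(sample$mask)
  if (stats::runif(1) < 0.5) sample <- flipSample(sample, "horizontal")
  if (stats::runif(1) < 0.5) sample <- flipSample(sample, "vertical")
  map <- identityMap(S)
  geo <- FALSE
  if (stats::runif(1) < 0.5) {        # rotation about the image centre
    a <- stats::runif(1, -rotationLimit, rotationLimit) * pi / 180
    c0 <- (S + 1) / 2
    di <- map$mi - c0; dj <- map$mj - c0
    map$mi <- c0 + cos(a) * di - sin(a) * dj
    map$mj <- c0 + sin(a) * di + cos(a) * dj
    geo <- TRUE
  }
  if (stats::runif(1) < 0.5) {        # crop-and-resize
    sc <- stats::runif(1, 0.7, 1)
    sz <- sc * (S - 1)
    oi <- stats::runif(1, 0, (S - 1) - sz)
    oj <- stats::runif(1, 0, (S - 1) - sz)
    map$mi <- 1 + oi + (map$mi - 1) * sz / (S - 1)
    map$mj <- 1 + oj + (map$mj - 1) * sz / (S - 1)
    geo <- TRUE
  }
  if (stats::runif(1) < 0.5) {        # elastic deformation
    map$mi <- map$mi + blurMatrix(matrix(stats::rnorm(S * S), S, S), elasticSigma) *
      elasticAlpha * 3
    map$mj <- map$mj + blurMatrix(matrix(stats::rnorm(S * S), S, S), elasticSigma) *
      elasticAlpha * 3
    geo <- TRUE
  }
  if (geo) sample <- warpSample(sample, map$mi, map$mj)
  occ <- sample(4L, 1L)
  sample$image <- switch(occ,
                         occlusionCutout(sample$image),
                         occlusionCoarseDropout(sample$image),
                         occlusionGridDistort(sample$image),
                         occlusionGridDropout(sample$image))
  sample
}

## ---- resizing (data loading / prediction) --------------------------------

#' Resize a matrix or image array
#'
#' @param x matrix `[H, W]` or array `[H, W, C]`.
#' @param newH,newW target extent.
#' @param method `"bilinear"` (images) or `"nearest"` (masks).
#' @export
resizeArray <- function(x, newH, newW, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  H <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  W <- if (is.matrix(x)) ncol(x) else dim(x)[2]
  sI <- H / newH; sJ <- W / newW
  mi <- matrix((seq_len(newH) - 0.5) * sI + 0.5, newH, newW)
  mj <- matrix((seq_len(newW) - 0.5) * sJ + 0.5, newH, newW, byrow = TRUE)
  if (is.matrix(x)) return(sampleMatrix(x, mi, mj, method))
  out <- array(0, c(newH, newW, dim(x)[3]))
  for (c in seq_len(dim(x)[3])) out[, , c] <- sampleMatrix(x[, , c], mi, mj, method)
  out
}
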