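#' @name synthdata
#' @title Deterministic synthetic lesion-image generator
#' @description
#' Generates endoscopy-like training images with no external downloads:
#' each image holds one to a few smooth, low-contrast, fuzzy-edged
#' star-convex blob lesions on a textured background, with a per-pixel
#' binary mask and a Canny-derived edge mask. Every sample is a pure
#' function of `(seed, index)`.
NULL

#' Synthetic data configuration
#'
#' @param imageSize image extent in pixels.
#' @param lesionCountRange integer range `[min, max]` of lesions per image.
#' @param radiusRange lesion base radius as a fraction of the image extent.
#' @param boundaryHarmonics number of radial harmonics perturbing each
#'   lesion boundary (star-convex shape).
#' @param harmonicAmplitude relative amplitude of the boundary perturbation.
#' @param contrast lesion/background intensity gap in `[0, 1]`; low values
#'   emulate lesions with colour similar to normal tissue.
#' @param edgeBlurSigma Gaussian blur of the lesion boundary in pixels
#'   (fuzzy edges).
#' @param textureNoiseSigma per-pixel intensity noise.
#' @param textureScale correlation length of the smooth background texture.
#' @param seed base seed; samples are reproducible from `(seed, index)`.
#' @export
synthConfig <- function(imageSize = 64L, lesionCountRange = c(1L, 3L),
                        radiusRange = c(0.08, 0.22), boundaryHarmonics = 4L,
                        harmonicAmplitude = 0.3, contrast = 0.35,
                        edgeBlurSigma = 1.5, textureNoiseSigma = 0.06,
                        textureScale = 8, seed = 1L) {
  if (lesionCountRange[1] < 1L) stop("lesion count minimum must be >= 1")
  if (contrast <= 0) stop("contrast must be positive")
  structure(list(imageSize = as.integer(imageSize),
                 lesionCountRange = as.integer(lesionCountRange),
                 radiusRange = radiusRange,
                 boundaryHarmonics = as.integer(boundaryHarmonics),
                 harmonicAmplitude = harmonicAmplitude,
                 contrast = contrast, edgeBlurSigma = edgeBlurSigma,
                 textureNoiseSigma = textureNoiseSigma,
                 textureScale = textureScale, seed = as.integer(seed)),
            class = "synthConfig")
}

drawBlobMask <- function(S, cfg) {
  cx <- stats::runif(1, 0.2, 0.8) * S
  cy <- stats::runif(1, 0.2, 0.8) * S
  r0 <- stats::runif(1, cfg$radiusRange[1], cfg$radiusRange[2]) * S
  ecc <- stats::runif(1, 0.7, 1.3)
  rot <- stats::runif(1, 0, pi)
  M <- cfg$boundaryHarmonics
  amp <- cfg$harmonicAmplitude * stats::runif(M, 0, 1) / seq_len(M)
  phase <- stats::runif(M, 0, 2 * pi)
  ii <- matrix(seq_len(S), S, S)
  jj <- matrix(seq_len(S), S, S, byrow = TRUE)
  di <- ii - cy; dj <- jj - cx
  # rotate, then scale one axis (elliptical base shape)
  u <- cos(rot) * dj + sin(rot) * di
  v <- (-sin(rot) * dj + cos(rot) * di) / ecc
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  rtheta <- r0
  for (m in seq_len(M)) {
    rtheta <- rtheta + r0 * amp[m] * cos((m + 1) * theta + phase[m])
  }
  (rho <= rtheta) * 1
}

#' Generate one synthetic sample
#'
#' Draws `k` star-convex blob lesions (elliptical base radius modulated by
#' a low-order random harmonic series), fills them with a
#' background-similar intensity offset by `contrast`, blurs the boundary,
#' and adds smooth background texture plus pixel noise. The mask is the
#' union of blob interiors before blurring; the edge mask is its Canny
#' edge.
#'
#' @param cfg a [synthConfig()].
#' @param index sample index; `(cfg$seed, index)` fully determines the
#'   sample.
#' @return object of class `segSample`: list with `image`
#'   (`[H, W, 3]` in `[0, 1]`), `mask` (`[H, W]` binary) and `edge`
#'   (`[H, W]` binary).
#' @export
genSample <- function(cfg, index = 1L) {
  S <- cfg$imageSize
  set.seed(deriveSeed(cfg$seed, index))
  mask <- NULL
  for (try in seq_len(100L)) {
    k <- sample(seq(cfg$lesionCountRange[1], cfg$lesionCountRange[2]), 1L)
    m <- matrix(0, S, S)
    for (l in seq_len(k)) m <- pmax(m, drawBlobMask(S, cfg))
    fg <- mean(m)
    if (fg > 0 && fg < 0.9) { mask <- m; break }
  }
  if (is.null(mask)) stop("generator produced empty/degenerate masks 100 times; check config")
  base <- stats::runif(1, 0.35, 0.6)
  texture <- blurMatrix(matrix(stats::rnorm(S * S), S, S), cfg$textureScale)
  if (stats::sd(texture) > 0) texture <- texture / stats::sd(texture) * 0.05
  soft <- if (cfg$edgeBlurSigma > 0) blurMatrix(mask, cfg$edgeBlurSigma) else mask
  sgn <- sample(c(-1, 1), 1L)
  chanBase <- base + stats::runif(3, -0.05, 0.05)
  chanWeight <- stats::runif(3, 0.8, 1)
  img <- array(0, c(S, S, 3))
  for (c in 1:3) {
    ch <- chanBase[c] + texture + sgn * cfg$contrast * chanWeight[c] * soft
    if (cfg$textureNoiseSigma > 0) {
      ch <- ch + matrix(stats::rnorm(S * S, sd = cfg$textureNoiseSigma), S, S)
    }
    img[, , c] <- pmin(pmax(ch, 0), 1)
  }
  structure(list(image = img, mask = mask,
                 edge = cannyEdgeMask(mask)),
            class = "segSample")
}

#' @export
print.segSample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("segSample: %d x %d image, foreground %.1f%%, %d edge px\n",
              d[1], d[2], 100 * mean(x$mask), sum(x$edge)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Writes `n` image/mask PNG pairs under `images/` and `masks/` plus a
#' tab-separated manifest and a YAML echo of the generator configuration.
#' Masks are written as 0/255 grayscale PNG and round-trip losslessly.
#'
#' @param cfg a [synthConfig()].
#' @param n number of samples.
#' @param dir output directory (created if missing).
#' @return path of the manifest file, invisibly.
#' @export
writeDataset <- function(cfg, n, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- data.frame(index = seq_len(n),
                     image = sprintf("images/sample_%04d.png", seq_len(n)),
                     mask = sprintf("masks/sample_%04d.png", seq_len(n)))
  for (i in seq_len(n)) {
    s <- genSample(cfg, i)
    png::writePNG(s$image, file.path(dir, rows$image[i]))
    png::writePNG(s$mask, file.path(dir, rows$mask[i]))
  }
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(rows, manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(manifest)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory containing `manifest.tsv`.
#' @param withEdges recompute Canny edge masks from the masks on load.
#' @return list of `segSample` objects.
#' @export
readDataset <- function(dir, withEdges = TRUE) {
  manifest <- file.path(dir, "manifest.tsv")
  if (!file.exists(manifest)) stop("no manifest.tsv under ", dir)
  rows <- utils::read.table(manifest, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  lapply(seq_len(nrow(rows)), function(i) {
    img <- png::readPNG(file.path(dir, rows$image[i]))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3L) img <- img[, , 1:3]
    m <- png::readPNG(file.path(dir, rows$mask[i]))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m <- (m >= 0.5) * 1
    structure(list(image = img, mask = m,
                   edge = if (withEdges) cannyEdgeMask(m) else NULL),
              class = "segSample")
  })
}
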