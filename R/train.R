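#' @name train
#' @title Training, evaluation and prediction
#' @description
#' SGD training with momentum, weight decay and a cosine-annealing
#' warm-restart schedule; per-epoch validation with the confusion-matrix
#' metrics; best-model tracking by validation mDice; checkpointing; and
#' batch prediction to PNG masks.
NULL

#' Training configuration
#'
#' @param lr initial learning rate (SGD).
#' @param momentum SGD momentum.
#' @param weightDecay L2 weight decay.
#' @param batchSize images per optimizer step.
#' @param maxEpochs training epochs.
#' @param warmRestartPeriod first cosine cycle length in epochs.
#' @param warmRestartMult cycle-length multiplier at each restart.
#' @param etaMin floor of the cosine schedule.
#' @param augment apply the augmentation suite to training batches.
#' @param valEvery run validation every this many epochs (the final epoch
#'   always validates).
#' @param weights a [lossWeights()].
#' @param lossCfg a [lossConfig()].
#' @param seed run seed (controls shuffling and augmentation).
#' @export
trainConfig <- function(lr = 0.01, momentum = 0.9, weightDecay = 1e-4,
                        batchSize = 4L, maxEpochs = 150L,
                        warmRestartPeriod = 10, warmRestartMult = 2,
                        etaMin = 0, augment = TRUE, valEvery = 1L,
                        weights = lossWeights(), lossCfg = lossConfig(),
                        seed = 1L) {
  if (lr <= 0 || batchSize < 1L || maxEpochs < 1L) {
    stop("lr, batchSize and maxEpochs must be positive")
  }
  structure(list(lr = lr, momentum = momentum, weightDecay = weightDecay,
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 warmRestartPeriod = warmRestartPeriod,
                 warmRestartMult = warmRestartMult, etaMin = etaMin,
                 augment = isTRUE(augment), valEvery = as.integer(valEvery),
                 weights = weights,
                 lossCfg = lossCfg, seed = as.integer(seed)),
            class = "trainConfig")
}

#' Cosine-annealing warm-restart learning rate
#'
#' @param t continuous epoch position (epoch + fraction through it).
#' @param lr0 initial learning rate.
#' @param T0 first cycle length in epochs.
#' @param mult cycle-length multiplier after each restart.
#' @param etaMin learning-rate floor.
#' @export
cosineWarmRestartLR <- function(t, lr0 = 0.01, T0 = 10, mult = 2, etaMin = 0) {
  Ti <- T0
  tc <- t
  while (tc >= Ti) {
    tc <- tc - Ti
    Ti <- Ti * mult
  }
  etaMin + (lr0 - etaMin) / 2 * (1 + cos(pi * tc / Ti))
}

#' Create a network
#'
#' @param cfg a [networkConfig()].
#' @param seed seed for weight initialization.
#' @return object of class `segNet` (parameter tree + configuration).
#' @export
createNetwork <- function(cfg, seed = 1L) {
  set.seed(as.integer(seed))
  structure(list(params = initNetwork(cfg), cfg = cfg), class = "segNet")
}

#' @export
print.segNet <- function(x, ...) {
  n <- 0
  wrapped <- wrapParamTree(x$params, requires_grad = FALSE)
  walkAgLeaves(wrapped, function(t, path) n <<- n + length(t$value))
  cat(sprintf("segNet: input %dx%d, stem width %d, %s parameters\n",
              x$cfg$inputSize, x$cfg$inputSize, x$cfg$stemBase,
              format(n, big.mark = ",")))
  invisible(x)
}

# rebuild a plain parameter tree from a wrapped one (after in-place updates
# of the tensor values during an optimizer step)
unwrapParamTree <- function(p) {
  if (agIs(p)) return(p$value)
  if (is.list(p) && !inherits(p, c("attentionConfig", "resStageConfig"))) {
    return(lapply(p, unwrapParamTree))
  }
  p
}

batchArrays <- function(samples) {
  S <- nrow(samples[[1]]$mask)
  N <- length(samples)
  x <- array(0, c(S, S, 3L, N))
  y <- array(0, c(S, S, 1L, N))
  e <- array(0, c(S, S, 1L, N))
  for (n in seq_len(N)) {
    x[, , , n] <- samples[[n]]$image
    y[, , 1L, n] <- samples[[n]]$mask
    if (!is.null(samples[[n]]$edge)) e[, , 1L, n] <- samples[[n]]$edge
  }
  list(x = x, y = y, e = e)
}

#' Split a sample list into train/validation/test sets
#'
#' @param samples list of `segSample`.
#' @param ratios relative sizes, default 8:1:1.
#' @param seed shuffle seed.
#' @export
splitDataset <- function(samples, ratios = c(8, 1, 1), seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(samples)
  idx <- sample.int(n)
  cuts <- round(cumsum(ratios) / sum(ratios) * n)
  list(train = samples[idx[seq_len(cuts[1])]],
       val = samples[idx[(cuts[1] + 1):cuts[2]]],
       test = if (cuts[3] > cuts[2]) samples[idx[(cuts[2] + 1):cuts[3]]] else list())
}

#' Train a network
#'
#' SGD with momentum, weight decay and the cosine warm-restart schedule;
#' each step augments a shuffled mini-batch, runs the forward pass in
#' batch-statistics mode, evaluates the composite loss on the segmentation
#' and edge logits, backpropagates and updates. Validation runs after
#' every epoch; the parameters with the best validation mDice are retained.
#'
#' @param net a `segNet` from [createNetwork()].
#' @param trainCfg a [trainConfig()].
#' @param data list with `train` and `val` lists of `segSample`.
#' @param verbose print one line per epoch.
#' @return list of class `runRecord`: the trained `net` (final and best
#'   parameters), per-epoch history, per-step loss trace, and the seed.
#' @export
trainModel <- function(net, trainCfg, data, verbose = FALSE) {
  stopifnot(inherits(net, "segNet"))
  set.seed(trainCfg$seed)
  params <- net$params
  cfg <- net$cfg
  vel <- list()
  history <- NULL
  stepLoss <- numeric(0)
  best <- list(dice = -Inf, params = NULL, epoch = NA_integer_)
  nTrain <- length(data$train)
  stepsPerEpoch <- ceiling(nTrain / trainCfg$batchSize)
  for (epoch in seq_len(trainCfg$maxEpochs)) {
    perm <- sample.int(nTrain)
    comp <- c(total = 0, bce = 0, dice = 0, ohem = 0)
    for (step in seq_len(stepsPerEpoch)) {
      lo <- (step - 1L) * trainCfg$batchSize + 1L
      hi <- min(step * trainCfg$batchSize, nTrain)
      batch <- data$train[perm[lo:hi]]
      if (trainCfg$augment) batch <- lapply(batch, augmentSample)
      ba <- batchArrays(batch)
      P <- wrapParamTree(params, requires_grad = TRUE)
      out <- agNetworkForward(agTensor(ba$x), P, cfg, training = TRUE)
      L <- agTotalLoss(out$seg, ba$y, out$edge, ba$e,
                       trainCfg$weights, trainCfg$lossCfg)
      lv <- agValue(L$loss)
      if (!is.finite(lv)) {
        stop(sprintf("non-finite loss at epoch %d step %d (bce=%.4g dice=%.4g ohem=%.4g)",
                     epoch, step, L$bce, L$dice, L$ohem))
      }
      agBackward(L$loss)
      lr <- cosineWarmRestartLR(epoch - 1 + (step - 1) / stepsPerEpoch,
                                trainCfg$lr, trainCfg$warmRestartPeriod,
                                trainCfg$warmRestartMult, trainCfg$etaMin)
      k <- 0L
      walkAgLeaves(P, function(t, path) {
        k <<- k + 1L
        g <- t$grad
        if (is.null(g)) g <- 0 * t$value
        g <- g + trainCfg$weightDecay * t$value
        v <- if (k > length(vel) || is.null(vel[[k]])) g
             else trainCfg$momentum * vel[[k]] + g
        vel[[k]] <<- v
        t$value <- t$value - lr * v
      })
      params <- unwrapParamTree(P)
      stepLoss <- c(stepLoss, lv)
      comp <- comp + c(lv, L$bce, L$dice, L$ohem)
    }
    comp <- comp / stepsPerEpoch
    net$params <- params
    doVal <- epoch == 1L || epoch %% trainCfg$valEvery == 0L ||
      epoch == trainCfg$maxEpochs
    if (!doVal) {
      history <- rbind(history, data.frame(
        epoch = epoch, trainLoss = comp[["total"]], bce = comp[["bce"]],
        dice = comp[["dice"]], ohem = comp[["ohem"]],
        valDice = NA_real_, valIou = NA_real_, valEdgeBce = NA_real_,
        lr = cosineWarmRestartLR(epoch - 1, trainCfg$lr,
                                 trainCfg$warmRestartPeriod,
                                 trainCfg$warmRestartMult, trainCfg$etaMin)))
      next
    }
    val <- evaluateModel(net, data$val, batchSize = max(8L, trainCfg$batchSize),
                         withEdgeBce = TRUE)
    if (val$aggregate$dice > best$dice) {
      best <- list(dice = val$aggregate$dice, params = paramTreeToList(params),
                   epoch = epoch)
    }
    history <- rbind(history, data.frame(
      epoch = epoch, trainLoss = comp[["total"]], bce = comp[["bce"]],
      dice = comp[["dice"]], ohem = comp[["ohem"]],
      valDice = val$aggregate$dice, valIou = val$aggregate$iou,
      valEdgeBce = val$edgeBce %||% NA_real_,
      lr = cosineWarmRestartLR(epoch - 1, trainCfg$lr,
                               trainCfg$warmRestartPeriod,
                               trainCfg$warmRestartMult, trainCfg$etaMin)))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val mDice %.4f  (best %.4f @ %d)",
                      epoch, comp[["total"]], val$aggregate$dice,
                      best$dice, best$epoch))
    }
  }
  net$params <- params
  structure(list(net = net, bestParams = best$params, bestEpoch = best$epoch,
                 bestValDice = best$dice, history = history,
                 stepLoss = stepLoss, seed = trainCfg$seed),
            class = "runRecord")
}

#' Restore the best-validation parameters of a run
#' @param record a `runRecord` from [trainModel()].
#' @return the `segNet` with the best-epoch parameters.
#' @export
bestNetwork <- function(record) {
  net <- record$net
  if (!is.null(record$bestParams)) net$params <- paramTreeFromList(record$bestParams)
  net
}

#' Evaluate a network on a sample list
#'
#' @param net a `segNet`.
#' @param samples list of `segSample`.
#' @param threshold binarization threshold.
#' @param batchSize forward-pass batch size.
#' @param withEdgeBce also report the mean BCE of the edge head.
#' @return list with `perImage` scores, `aggregate` means, and optionally
#'   `edgeBce`.
#' @export
evaluateModel <- function(net, samples, threshold = 0.5, batchSize = 8L,
                          withEdgeBce = FALSE) {
  perImage <- vector("list", length(samples))
  edgeBce <- 0
  nb <- 0L
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + batchSize - 1L, length(samples))
    ba <- batchArrays(samples[i:j])
    out <- networkForward(ba$x, net$params, net$cfg, training = FALSE)
    prob <- 1 / (1 + exp(-out$seg))
    for (n in seq_len(j - i + 1L)) {
      perImage[[i + n - 1L]] <- confusionScores(
        confusionCounts(prob[, , 1L, n], ba$y[, , 1L, n], threshold))
    }
    if (withEdgeBce && !is.null(out$edge)) {
      ep <- 1 / (1 + exp(-out$edge))
      edgeBce <- edgeBce + bceLoss(ep, ba$e)
      nb <- nb + 1L
    }
    i <- j + 1L
  }
  out <- list(perImage = perImage, aggregate = aggregateScores(perImage))
  if (withEdgeBce && nb > 0L) out$edgeBce <- edgeBce / nb
  out
}

#' Save / load a checkpoint
#'
#' Checkpoints hold the parameter tree (with batch-norm running statistics
#' materialized), the network configuration, and optional metadata.
#'
#' @param net a `segNet`.
#' @param path checkpoint file.
#' @param meta optional metadata list.
#' @export
saveCheckpoint <- function(net, path, meta = NULL) {
  saveRDS(list(params = paramTreeToList(net$params), cfg = net$cfg,
               meta = meta), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  structure(list(params = paramTreeFromList(ck$params), cfg = ck$cfg,
                 meta = ck$meta), class = "segNet")
}

#' Predict masks for a directory of images
#'
#' Each readable image is resized to the network input size, segmented,
#' thresholded at 0.5 and written as a 0/255 PNG at the original extent.
#'
#' @param net a `segNet`.
#' @param imagesDir directory of input PNGs.
#' @param outDir output directory.
#' @param writeProb also write the probability map as a PNG.
#' @return character vector of written mask paths.
#' @export
predictMasks <- function(net, imagesDir, outDir, writeProb = FALSE) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- sort(list.files(imagesDir, pattern = "\\.png$", full.names = TRUE))
  S <- net$cfg$inputSize
  written <- character(0)
  for (f in files) {
    img <- tryCatch(png::readPNG(f), error = function(e) NULL)
    if (is.null(img)) {
      warning("skipping unreadable image: ", f)
      next
    }
    if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
    if (dim(img)[3] > 3L) img <- img[, , 1:3]
    d0 <- dim(img)[1:2]
    x <- array(resizeArray(img, S, S, "bilinear"), c(S, S, 3L, 1L))
    out <- networkForward(x, net$params, net$cfg, training = FALSE)
    prob <- 1 / (1 + exp(-out$seg[, , 1L, 1L]))
    mask <- (prob >= 0.5) * 1
    if (any(d0 != c(S, S))) mask <- resizeArray(mask, d0[1], d0[2], "nearest")
    op <- file.path(outDir, basename(f))
    png::writePNG(mask, op)
    if (writeProb) {
      pr <- if (any(d0 != c(S, S))) resizeArray(prob, d0[1], d0[2], "bilinear") else prob
      png::writePNG(pr, file.path(outDir, sub("\\.png$", "_prob.png", basename(f))))
    }
    written <- c(written, op)
  }
  written
}
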