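#' @name experiments
#' @title Desk-scale reference experiments
#' @description
#' The two standard synthetic experiments the package uses to validate the
#' full training pipeline on one CPU core: an overfit sanity check (8 fixed
#' samples, 200 optimizer steps) and a generalization run (200 training
#' samples, 50 unseen holdout samples, 12 epochs) on the desk-scale
#' network. All randomness derives from one seed.
NULL

#' Overfit sanity experiment
#'
#' Trains the desk-scale network on 8 fixed synthetic samples for
#' `steps` full-batch optimizer steps without augmentation and reports the
#' training-set mDice (evaluation mode). A healthy implementation drives
#' it close to 1.
#'
#' @param seed master seed (generator, initialization and run seeds derive
#'   from it).
#' @param steps optimizer steps (one per epoch at full batch).
#' @param verbose print progress.
#' @return list with `trainDice`, `edgeBceFirst`, `edgeBceLast` and the
#'   full `record`.
#' @export
overfitExperiment <- function(seed = 1L, steps = 200L, verbose = FALSE) {
  sc <- synthConfig(seed = as.integer(deriveSeed(seed, 101)))
  samples <- lapply(1:8, function(i) genSample(sc, i))
  net <- createNetwork(tinyNetworkConfig(),
                       seed = as.integer(deriveSeed(seed, 102)))
  tc <- trainConfig(batchSize = 8L, maxEpochs = as.integer(steps),
                    augment = FALSE, valEvery = 10L,
                    seed = as.integer(deriveSeed(seed, 103)))
  rec <- trainModel(net, tc, list(train = samples, val = samples),
                    verbose = verbose)
  h <- rec$history
  hv <- h[!is.na(h$valDice), ]
  list(trainDice = hv$valDice[nrow(hv)],
       edgeBceFirst = hv$valEdgeBce[1],
       edgeBceLast = hv$valEdgeBce[nrow(hv)],
       record = rec)
}

#' Synthetic generalization experiment
#'
#' Trains the desk-scale network on `nTrain` synthetic samples with the
#' full augmentation suite and evaluates the best-validation parameters on
#' `nHoldout` unseen samples from the same generator.
#'
#' @inheritParams overfitExperiment
#' @param nTrain training samples.
#' @param nHoldout unseen holdout samples.
#' @param epochs training epochs (default: one full cosine cycle).
#' @return list with `holdout` (aggregate metrics of the best model on the
#'   holdout set) and the full `record`.
#' @export
generalizationExperiment <- function(seed = 1L, nTrain = 200L,
                                     nHoldout = 50L, epochs = 10L,
                                     verbose = FALSE) {
  sc <- synthConfig(seed = as.integer(deriveSeed(seed, 201)))
  train <- lapply(seq_len(nTrain), function(i) genSample(sc, i))
  hold <- lapply(nTrain + seq_len(nHoldout), function(i) genSample(sc, i))
  net <- createNetwork(tinyNetworkConfig(),
                       seed = as.integer(deriveSeed(seed, 202)))
  tc <- trainConfig(batchSize = 8L, maxEpochs = as.integer(epochs),
                    augment = TRUE, valEvery = 2L,
                    seed = as.integer(deriveSeed(seed, 203)))
  rec <- trainModel(net, tc, list(train = train, val = hold),
                    verbose = verbose)
  best <- bestNetwork(rec)
  res <- evaluateModel(best, hold)
  list(holdout = res$aggregate, record = rec)
}
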