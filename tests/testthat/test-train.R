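# training plumbing: the warm-restart schedule, dataset splitting,
# checkpoint round-trips, evaluation upper bound, prediction contracts and
# the CLI surface (no long optimizations here; those live in the
# acceptance suite)

test_that("cosine warm-restart schedule starts at lr0 and jumps at restarts", {
  expect_equal(cosineWarmRestartLR(0, 0.01, 10, 2), 0.01)
  justBefore <- cosineWarmRestartLR(10 - 1e-6, 0.01, 10, 2)
  justAfter <- cosineWarmRestartLR(10, 0.01, 10, 2)
  expect_lt(justBefore, 1e-6)
  expect_equal(justAfter, 0.01)
  expect_lt(justBefore, justAfter)
  # second cycle is twice as long
  expect_equal(cosineWarmRestartLR(10 + 10, 0.01, 10, 2),
               0.01 / 2 * (1 + cos(pi * 0.5)))
  # monotone decay inside a cycle
  ts <- seq(0, 9.9, by = 0.1)
  expect_true(all(diff(vapply(ts, cosineWarmRestartLR, numeric(1), lr0 = 0.01)) < 0))
})

test_that("dataset split honours the 8:1:1 ratio and is reproducible", {
  samples <- as.list(1:100)
  sp <- splitDataset(samples, seed = 4)
  expect_length(sp$train, 80L)
  expect_length(sp$val, 10L)
  expect_length(sp$test, 10L)
  expect_length(unique(c(unlist(sp$train), unlist(sp$val), unlist(sp$test))), 100L)
  sp2 <- splitDataset(samples, seed = 4)
  expect_identical(sp, sp2)
})

test_that("checkpoints round-trip parameters, config and predictions", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 201)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f, meta = list(note = "test"))
  back <- loadCheckpoint(f)
  expect_equal(back$cfg, net$cfg)
  expect_equal(back$meta$note, "test")
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  expect_equal(networkForward(x, back$params, back$cfg)$seg,
               networkForward(x, net$params, net$cfg)$seg, tolerance = 1e-14)
  unlink(f)
})

test_that("evaluating the ground truth as prediction scores 1 everywhere", {
  cfg <- synthConfig(seed = 12)
  samples <- lapply(1:4, function(i) genSample(cfg, i))
  perImage <- lapply(samples, function(s) {
    confusionScores(confusionCounts(s$mask, s$mask))
  })
  agg <- aggregateScores(perImage)
  expect_equal(unlist(agg), c(dice = 1, iou = 1, precision = 1, recall = 1))
})

test_that("prediction writes one binary PNG per readable input, deterministically", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 202)
  imgDir <- file.path(tempdir(), "predin")
  outDir1 <- file.path(tempdir(), "predout1")
  outDir2 <- file.path(tempdir(), "predout2")
  unlink(c(imgDir, outDir1, outDir2), recursive = TRUE)
  dir.create(imgDir, recursive = TRUE)
  sc <- synthConfig(seed = 13)
  for (i in 1:3) {
    png::writePNG(genSample(sc, i)$image, file.path(imgDir, sprintf("im%d.png", i)))
  }
  writeLines("not a png", file.path(imgDir, "broken.png"))
  expect_warning(out1 <- predictMasks(net, imgDir, outDir1), "unreadable")
  expect_length(out1, 3L)
  for (f in out1) {
    m <- png::readPNG(f)
    expect_true(all(m %in% c(0, 1)))   # 0/255 bytes read back as 0/1
  }
  suppressWarnings(predictMasks(net, imgDir, outDir2))
  for (f in basename(out1)) {
    expect_identical(readBin(file.path(outDir1, f), "raw", 1e6),
                     readBin(file.path(outDir2, f), "raw", 1e6))
  }
  unlink(c(imgDir, outDir1, outDir2), recursive = TRUE)
})

test_that("the CLI synth verb writes a dataset and eval reports metrics", {
  d <- file.path(tempdir(), "clids")
  unlink(d, recursive = TRUE)
  expect_message(
    cliMain(c("synth", "--out", d, "--nSamples", "4", "--imageSize", "64",
              "--seed", "3")),
    "wrote 4 samples")
  expect_length(list.files(file.path(d, "images")), 4L)
  expect_true(file.exists(file.path(d, "config.yaml")))
  samples <- readDataset(d)
  expect_length(samples, 4L)
  unlink(d, recursive = TRUE)
})

test_that("training aborts with a diagnostic on non-finite loss", {
  cfg <- tinyNetworkConfig()
  net <- createNetwork(cfg, seed = 203)
  # poison one weight so the forward pass blows up
  net$params$head$b <- NaN
  sc <- synthConfig(seed = 14)
  samples <- lapply(1:2, function(i) genSample(sc, i))
  tc <- trainConfig(batchSize = 2L, maxEpochs = 1L, augment = FALSE, seed = 1L)
  expect_error(trainModel(net, tc, list(train = samples, val = samples)),
               "non-finite")
})

test_that("the full CLI loop (synth, train, eval, predict) round-trips", {
  base <- file.path(tempdir(), "cliloop")
  unlink(base, recursive = TRUE)
  dir.create(base)
  d <- file.path(base, "data"); ck <- file.path(base, "model.rds")
  mx <- file.path(base, "metrics.tsv"); pd <- file.path(base, "preds")
  suppressMessages(cliMain(c("synth", "--out", d, "--nSamples", "10",
                             "--imageSize", "64", "--seed", "2")))
  suppressMessages(cliMain(c("train", "--data", d, "--out", ck,
                             "--maxEpochs", "1", "--batchSize", "4",
                             "--seed", "2")))
  expect_true(file.exists(ck))
  suppressMessages(cliMain(c("eval", "--checkpoint", ck, "--data", d,
                             "--out", mx, "--seed", "2")))
  tab <- read.table(mx, header = TRUE, sep = "\t")
  expect_equal(nrow(tab), 11L)   # 10 images + aggregate
  suppressMessages(cliMain(c("predict", "--checkpoint", ck,
                             "--images", file.path(d, "images"),
                             "--out", pd, "--seed", "2")))
  expect_length(list.files(pd), 10L)
  unlink(base, recursive = TRUE)
})
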