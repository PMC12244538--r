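# The segmentation network: architecture, focal loss, gradients, training
# mechanics, prediction and post-processing.

tinyConfig <- function(side = 32L, ws = 0.04, seed = 5L, ...) {
  cdlConfig(inputSide = side, widthScale = ws, seed = seed, dropout = 0, ...)
}

test_that("the built network has the declared architecture", {
  net <- buildCDL(tinyConfig())
  expect_equal(net$nConvLayers, 13L)
  expect_equal(net$nFCEquivalent, 3L)
  expect_equal(net$nSkips, 3L)
  convNames <- grep("^conv", names(net$layers), value = TRUE)
  expect_length(convNames, 13L)
  for (nm in c("skip1", "skip2", "skip3"))
    expect_equal(c(net$layers[[nm]]$kh, net$layers[[nm]]$kw), c(1L, 1L))
  expect_error(cdlConfig(inputSide = 16, seed = 1), "nearest valid side is 32")
  # width scaling changes channels, never structure
  wide <- buildCDL(cdlConfig(inputSide = 32, widthScale = 0.1, seed = 1))
  expect_identical(names(wide$layers), names(net$layers))
})

test_that("the forward map preserves spatial size at odd input sides", {
  for (side in c(32L, 45L)) {
    net <- buildCDL(tinyConfig(side = side))
    x <- array(runif(side * side * 3) - 0.5, c(side, side, 3))
    prob <- mitoscope:::forwardCDL(net, x)$prob
    expect_equal(dim(prob), c(side, side))
    expect_true(all(prob >= 0 & prob <= 1))
  }
})

test_that("focal loss reduces to cross-entropy and matches hand arithmetic", {
  set.seed(2)
  p <- runif(1000, 0.01, 0.99)
  y <- rbinom(1000, 1, 0.5)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(focalLoss(p, y, alpha = 1, gamma = 0), bce,
               tolerance = 1e-12)
  expect_equal(focalLoss(0.9, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.1^2 * (-log(0.9)), tolerance = 1e-12)
  expect_lt(focalLoss(rep(1, 10), rep(1, 10), 0.25, 2), 1e-12)
  # monotone non-increasing in p_t
  pts <- seq(0.05, 0.95, by = 0.05)
  losses <- vapply(pts, function(q) focalLoss(q, 1, 0.25, 2), numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_error(focalLoss(c(0.5, 0.5), 1, 0.25, 2), "shapes")
})

test_that("analytic gradients match finite differences through the graph", {
  net <- buildCDL(tinyConfig())
  set.seed(1)
  x <- array(runif(32 * 32 * 3) - 0.5, c(32, 32, 3))
  target <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
  fw <- mitoscope:::forwardCDL(net, x, train = TRUE)
  dL <- array(mitoscope:::focalLossGradLogit(fw$prob, target, 0.25, 2),
              c(32, 32, 1))
  grads <- mitoscope:::backwardCDL(net, fw$cache, dL)
  eps <- 1e-6
  for (nm in c("conv1_1", "conv4_2", "fc6", "score", "skip1", "skip3",
               "up3", "up4")) {
    W <- net$layers[[nm]]$W
    i <- sample(length(W), 1)
    net2 <- net
    net2$layers[[nm]]$W[i] <- W[i] + eps
    lp <- focalLoss(mitoscope:::forwardCDL(net2, x)$prob, target, 0.25, 2)
    net2$layers[[nm]]$W[i] <- W[i] - eps
    lm <- focalLoss(mitoscope:::forwardCDL(net2, x)$prob, target, 0.25, 2)
    num <- (lp - lm) / (2 * eps)
    expect_equal(grads[[nm]]$dW[i], num, tolerance = 1e-4)
  }
})

test_that("weight transfer tags layers and never downloads", {
  net <- buildCDL(tinyConfig())
  same <- transferWeights(net, "none")
  expect_identical(same$layers$conv1_1$W, net$layers$conv1_1$W)
  # same seed, same initialization, bitwise
  net2 <- buildCDL(tinyConfig())
  expect_identical(net$layers$conv3_2$W, net2$layers$conv3_2$W)
  expect_error(
    withr::with_options(list(mitoscope.weightsDir = tempfile("nope")),
                        transferWeights(net, "vgg")),
    "weight file not found")
  # a provided weight file is loaded, truncated and tagged
  dir <- tempfile("weights"); dir.create(dir)
  src <- list(list(W = matrix(seq_len(27 * 64) / 1000, 27, 64),
                   b = seq_len(64) / 100),
              list(W = matrix(seq_len(9 * 64 * 64) / 1e5, 9 * 64, 64),
                   b = numeric(64)))
  saveRDS(src, file.path(dir, "vgg_conv.rds"))
  tr <- withr::with_options(list(mitoscope.weightsDir = dir),
                            transferWeights(net, "vgg"))
  expect_true(tr$layers$conv1_1$pretrained)
  expect_true(tr$layers$conv1_2$pretrained)
  expect_false(isTRUE(tr$layers$conv2_1$pretrained))
  expect_equal(tr$layers$conv1_1$W[1, 1], src[[1]]$W[1, 1])
})

test_that("augmentation preserves masks and bounds", {
  tile <- smokeTiles(1, seedBase = 60)[[1]]
  fg <- sum(tileMask(tile))
  for (s in 1:20) {
    set.seed(s)
    aug <- augmentTile(tile)
    expect_equal(sum(tileMask(aug)), fg)
    expect_true(min(tilePixels(aug)) >= 0 && max(tilePixels(aug)) <= 255)
  }
  # flips are involutions applied jointly to image and mask
  set.seed(3)
  flipped <- augmentTile(tile)
  px <- tilePixels(flipped)
  expect_equal(dim(px), dim(tilePixels(tile)))
})

test_that("early stopping fires after the configured patience", {
  tiles <- smokeTiles(4, seedBase = 70, side = 32, nNuclei = 4,
                      nMitotic = 1)
  # zero learning rates: validation loss can never improve after epoch 1
  cfg <- cdlConfig(inputSide = 32, widthScale = 0.04, seed = 2,
                   lrNew = 0, lrPretrained = 0, batchSize = 2,
                   maxEpochs = 50, patience = 5, dropout = 0)
  st <- trainCDL(buildCDL(cfg), tiles[1:2], tiles[3:4], cfg,
                 augment = FALSE)
  expect_true(st@stoppedEarly)
  expect_equal(st@epoch, 6L)
  expect_lte(st@epoch, cfg$maxEpochs)
  expect_equal(st@epochsSinceImprovement, cfg$patience)
})

test_that("a desk-scale network learns easy tiles and stays deterministic", {
  tiles <- smokeTiles(10, seedBase = 80, side = 32, nNuclei = 4,
                      nMitotic = 1)
  cfg <- cdlConfig(inputSide = 32, widthScale = 0.1, seed = 4,
                   batchSize = 4, maxEpochs = 8, patience = 8)
  st <- trainCDL(buildCDL(cfg), tiles[1:8], tiles[9:10], cfg)
  expect_lt(tail(st@history$trainLoss, 1), st@history$trainLoss[1])
  st2 <- trainCDL(buildCDL(cfg), tiles[1:8], tiles[9:10], cfg)
  expect_identical(st@history, st2@history)
})

test_that("prediction warns when untrained and bounds its output", {
  net <- buildCDL(tinyConfig())
  tile <- smokeTiles(1, seedBase = 90, side = 32, nNuclei = 4,
                     nMitotic = 1)[[1]]
  expect_warning(prob <- predictSegmentation(net, tile), "not been trained")
  expect_equal(dim(prob), c(32L, 32L))
  expect_true(all(prob >= 0 & prob <= 1))
})

test_that("post-processing filters, measures and ranks detections", {
  expect_equal(nrow(postprocessDetections(matrix(0, 30, 30))), 0L)
  pm <- matrix(0, 40, 40)
  disk <- diskMask(40, 4, ctr = 12)
  pm[disk == 1] <- 0.9
  det <- postprocessDetections(pm)
  expect_equal(nrow(det), 1L)
  expect_equal(det$area, sum(disk))
  expect_equal(det$score, 0.9, tolerance = 1e-12)
  expect_equal(det$row, mean(which(disk == 1, arr.ind = TRUE)[, 1]) - 1)
  # small blob below minArea is dropped
  pm[35:36, 35:36] <- 0.99
  det2 <- postprocessDetections(pm, minArea = 10)
  expect_equal(nrow(det2), 1L)
  # ranking by score
  pm2 <- pm
  pm2[30:36, 30:36] <- 0.7
  det3 <- postprocessDetections(pm2, minArea = 10)
  expect_equal(det3$score, sort(det3$score, decreasing = TRUE))
})

test_that("checkpoints round-trip the network", {
  net <- buildCDL(tinyConfig())
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(net, f, registryVersion = "1.0")
  back <- loadCheckpoint(f)
  expect_identical(back$layers$conv1_1$W, net$layers$conv1_1$W)
  expect_equal(back$config$inputSide, net$config$inputSide)
  expect_equal(back$registryVersion, "1.0")
})
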