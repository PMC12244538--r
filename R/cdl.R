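# The CDL detector: a VGG-16-style backbone (13 convolutional layers)
# converted to a fully convolutional network, with the three former FC
# layers realized as 1x1 convolutions (the last replaced by a fresh 1-channel
# scoring layer), three 1x1-convolution skip connections tapping the pool4 /
# pool3 / pool2 outputs, staged transposed-convolution upsampling with
# center cropping back to the input size, focal loss, optional transferred
# early-layer weights, augmentation, and early-stopped Adam training.

#' CDL network configuration
#'
#' Defaults follow the reported settings: 227 x 227 inputs, focal loss with
#' alpha 0.25 / gamma 2, learning rates 1e-5 for transferred layers and
#' 1e-3 elsewhere, batch size 32, at most 100 epochs with early-stopping
#' patience 5, dropout 0.3 on the FC-equivalent layers and L2 coefficient
#' 1e-4.
#'
#' @param inputSide input side length in pixels (>= 32).
#' @param widthScale channel-count scale in (0, 1\]; 1 is the full backbone,
#'   smaller values give a structurally identical desk-scale network (layer
#'   structure is never changed).
#' @param focalAlpha,focalGamma focal-loss parameters.
#' @param lrPretrained,lrNew learning rates for transferred / new layers.
#' @param batchSize minibatch size.
#' @param maxEpochs epoch budget.
#' @param patience early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param dropout dropout rate on FC-equivalent layers.
#' @param l2 L2 regularization coefficient.
#' @param seed integer seed (mandatory).
#' @param pretrainedSource `"vgg"`, `"alexnet"` or `"none"`.
#' @return validated configuration list of class `CDLConfig`.
#' @export
cdlConfig <- function(inputSide = 227L, widthScale = 1, focalAlpha = 0.25,
                      focalGamma = 2, lrPretrained = 1e-5, lrNew = 1e-3,
                      batchSize = 32L, maxEpochs = 100L, patience = 5L,
                      dropout = 0.3, l2 = 1e-4, seed,
                      pretrainedSource = c("none", "vgg", "alexnet")) {
  if (missing(seed)) stop("cdlConfig: seed is mandatory")
  pretrainedSource <- match.arg(pretrainedSource)
  stopifnot(widthScale > 0, widthScale <= 1, focalGamma >= 0, patience >= 1L,
            batchSize >= 1L, maxEpochs >= 1L, dropout >= 0, dropout < 1)
  if (inputSide < 32L)
    stop("cdlConfig: inputSide ", inputSide, " is not reachable by the ",
         "stride schedule; nearest valid side is 32")
  structure(list(inputSide = as.integer(inputSide), widthScale = widthScale,
                 nSkips = 3L, focalAlpha = focalAlpha,
                 focalGamma = focalGamma, lrPretrained = lrPretrained,
                 lrNew = lrNew, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), dropout = dropout,
                 l2 = l2, seed = as.integer(seed),
                 pretrainedSource = pretrainedSource), class = "CDLConfig")
}

# VGG-16 convolutional channel plan, grouped into the five blocks
cdlChannelPlan <- function(widthScale) {
  base <- c(64, 64, 128, 128, 256, 256, 256, 512, 512, 512, 512, 512, 512)
  list(conv = pmax(1L, as.integer(round(widthScale * base))),
       fc = max(8L, as.integer(round(widthScale * 4096))))
}

heConv <- function(kh, kw, cin, cout) {
  list(W = matrix(rnorm(kh * kw * cin * cout, 0,
                        sqrt(2 / (kh * kw * cin))), kh * kw * cin, cout),
       b = numeric(cout), kh = kh, kw = kw, lrGroup = "new",
       pretrained = FALSE)
}

# bilinear-interpolation initialization for a k x k / stride s transposed
# convolution (the standard upsampling start)
bilinearKernel <- function(k, s) {
  f <- (k + 1) / 2 - 0.5 * (k %% 2 == 0)
  center <- (k - 1) / 2
  v <- 1 - abs((0:(k - 1)) - center) / f
  outer(v, v)
}

#' Build the CDL network specification
#'
#' The full-width network has 13 convolutional layers (3x3, same padding,
#' ReLU) in the VGG-16 block layout, three FC-equivalent 1x1 convolutions
#' (the final one a fresh 1-channel scoring layer), three 1x1-convolution
#' skip connections tapping pool4, pool3 and pool2, and four transposed
#' convolution upsampling stages (three x2, one final x4) with center
#' cropping, so the output probability map matches the input size exactly.
#' Weight initialization is seeded from the configuration.
#'
#' @param config a [cdlConfig()] list.
#' @return a network specification (list) consumed by [trainCDL()] and
#'   [predictSegmentation()].
#' @export
#' @examples
#' net <- buildCDL(cdlConfig(inputSide = 64, widthScale = 0.05, seed = 1))
#' net$nConvLayers
buildCDL <- function(config) {
  stopifnot(inherits(config, "CDLConfig"))
  plan <- cdlChannelPlan(config$widthScale)
  ch <- plan$conv
  blocks <- list(1:2, 3:4, 5:7, 8:10, 11:13)
  side <- config$inputSide
  sizes <- integer(5)
  s <- side
  for (i in 1:5) { s <- (s + 1L) %/% 2L; sizes[i] <- s }
  withSeed(config$seed, {
    layers <- list()
    cin <- 3L
    for (b in seq_along(blocks)) {
      for (li in blocks[[b]]) {
        layers[[sprintf("conv%d_%d", b, which(blocks[[b]] == li))]] <-
          heConv(3L, 3L, cin, ch[li])
        cin <- ch[li]
      }
    }
    layers$fc6 <- heConv(1L, 1L, ch[13], plan$fc)
    layers$fc7 <- heConv(1L, 1L, plan$fc, plan$fc)
    layers$score <- heConv(1L, 1L, plan$fc, 1L)
    layers$skip1 <- heConv(1L, 1L, ch[10], 1L)  # pool4 tap
    layers$skip2 <- heConv(1L, 1L, ch[7], 1L)   # pool3 tap
    layers$skip3 <- heConv(1L, 1L, ch[4], 1L)   # pool2 tap
    # skip fusions start as near-pass-through: small skip weights avoid
    # drowning the deep path at initialization
    for (nm in c("skip1", "skip2", "skip3"))
      layers[[nm]]$W <- layers[[nm]]$W * 0.01
    for (nm in c("up1", "up2", "up3")) {
      layers[[nm]] <- list(W = array(bilinearKernel(4L, 2L), c(4, 4, 1, 1)),
                           b = 0, k = 4L, s = 2L, lrGroup = "new",
                           pretrained = FALSE, kind = "convtr")
    }
    layers$up4 <- list(W = array(bilinearKernel(8L, 4L), c(8, 8, 1, 1)),
                       b = 0, k = 8L, s = 4L, lrGroup = "new",
                       pretrained = FALSE, kind = "convtr")
    list(layers = layers, config = config, sizes = sizes,
         nConvLayers = 13L, nFCEquivalent = 3L, nSkips = 3L,
         trained = FALSE)
  })
}

#' Focal loss
#'
#' Mean over pixels of `-alpha * (1 - p_t)^gamma * log(p_t)`, where `p_t`
#' is the probability assigned to the true class. Probabilities are clamped
#' to `[1e-7, 1 - 1e-7]`. With `gamma = 0`, `alpha = 1` this equals mean
#' binary cross-entropy exactly.
#'
#' @param probabilities per-pixel foreground probabilities.
#' @param targets binary mask of the same shape.
#' @param alpha weighting factor (constant over classes).
#' @param gamma focusing exponent, >= 0.
#' @return scalar loss.
#' @export
#' @examples
#' focalLoss(0.9, 1, alpha = 0.25, gamma = 2)
focalLoss <- function(probabilities, targets, alpha = 0.25, gamma = 2) {
  if (length(probabilities) != length(targets))
    stopShape("focalLoss: probabilities and targets shapes differ")
  p <- clampRange(probabilities, 1e-7, 1 - 1e-7)
  pt <- ifelse(targets == 1, p, 1 - p)
  mean(-alpha * (1 - pt)^gamma * log(pt))
}

# d(mean focal loss)/d(logit), elementwise, for sigmoid outputs
focalLossGradLogit <- function(prob, targets, alpha, gamma) {
  p <- clampRange(prob, 1e-7, 1 - 1e-7)
  y <- targets
  pt <- ifelse(y == 1, p, 1 - p)
  dLdpt <- alpha * gamma * (1 - pt)^(pmax(gamma - 1, 0)) * log(pt) -
    alpha * (1 - pt)^gamma / pt
  if (gamma == 0) dLdpt <- -alpha / pt
  dptdz <- p * (1 - p) * ifelse(y == 1, 1, -1)
  dLdpt * dptdz / length(p)
}

#' Transfer early-layer weights into a network
#'
#' With `source = "none"` the (already seeded-random) weights are left
#' unchanged. Otherwise the first `nLayers` convolutional layers are loaded
#' from a weight file expected at
#' `file.path(getOption("mitoscope.weightsDir", "~/.mitoscope"),
#' paste0(source, "_conv.rds"))` — an RDS list of `list(W, b)` per layer —
#' shape-adapted by leading-channel truncation when `widthScale < 1`, and
#' tagged to receive the pretrained learning rate. Missing files are an
#' error naming the expected path; nothing is ever downloaded.
#'
#' @param net a network from [buildCDL()].
#' @param source `"vgg"`, `"alexnet"` or `"none"`.
#' @param nLayers number of leading conv layers to transfer (default 2).
#' @return the updated network.
#' @export
transferWeights <- function(net, source = c("none", "vgg", "alexnet"),
                            nLayers = 2L) {
  source <- match.arg(source)
  if (source == "none") return(net)
  dir <- getOption("mitoscope.weightsDir", path.expand("~/.mitoscope"))
  path <- file.path(dir, paste0(source, "_conv.rds"))
  if (!file.exists(path))
    stop("transferWeights: pretrained weight file not found at '", path,
         "'; place the exported ", source, " convolutional weights there ",
         "(no download is ever attempted)")
  src <- readRDS(path)
  names13 <- c("conv1_1", "conv1_2", "conv2_1", "conv2_2")
  for (i in seq_len(nLayers)) {
    nm <- names13[i]
    tgt <- net$layers[[nm]]
    W <- src[[i]]$W
    keepIn <- seq_len(nrow(tgt$W) / (tgt$kh * tgt$kw))
    keepOut <- seq_len(ncol(tgt$W))
    # leading-channel truncation to the scaled shape
    Wa <- array(W, c(tgt$kh * tgt$kw, nrow(W) / (tgt$kh * tgt$kw), ncol(W)))
    Wt <- Wa[, keepIn, keepOut, drop = FALSE]
    net$layers[[nm]]$W <- matrix(Wt, nrow(tgt$W), ncol(tgt$W))
    net$layers[[nm]]$b <- src[[i]]$b[keepOut]
    net$layers[[nm]]$pretrained <- TRUE
    net$layers[[nm]]$lrGroup <- "pretrained"
  }
  net
}

#' Augment a tile
#'
#' Independent coin flips for horizontal and vertical flips (mask flipped
#' identically), brightness offset U(-20, 20) intensity levels and contrast
#' gain U(0.8, 1.2) about the tile mean, clipped to \[0, 255\]. Uses the
#' current RNG state.
#'
#' @param tile a preprocessed [HistologyTile-class].
#' @return the augmented [HistologyTile-class].
#' @export
augmentTile <- function(tile) {
  px <- tile@pixels
  mask <- tile@mask
  if (runif(1) < 0.5) {
    px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
    if (!is.null(mask)) mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  if (runif(1) < 0.5) {
    px <- px[rev(seq_len(dim(px)[1])), , , drop = FALSE]
    if (!is.null(mask)) mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
  }
  offset <- runif(1, -20, 20)
  gain <- runif(1, 0.8, 1.2)
  m <- mean(px)
  px <- clampRange((px - m) * gain + m + offset, 0, 255)
  histologyTile(px, mask = mask, id = tile@id, splitTag = tile@splitTag)
}

reluFwd <- function(x) { x[x < 0] <- 0; x }

cropCenter <- function(x, target) {
  off1 <- (dim(x)[1] - target) %/% 2L
  off2 <- (dim(x)[2] - target) %/% 2L
  x[(off1 + 1L):(off1 + target), (off2 + 1L):(off2 + target), , drop = FALSE]
}

padToFull <- function(dy, fullH, fullW) {
  out <- array(0, c(fullH, fullW, dim(dy)[3]))
  off1 <- (fullH - dim(dy)[1]) %/% 2L
  off2 <- (fullW - dim(dy)[2]) %/% 2L
  out[(off1 + 1L):(off1 + dim(dy)[1]),
      (off2 + 1L):(off2 + dim(dy)[2]), ] <- dy
  out
}

# forward pass; when train = TRUE, caches everything backward needs
forwardCDL <- function(net, x, train = FALSE) {
  L <- net$layers
  drop <- net$config$dropout
  cache <- list(x = x)
  convRelu <- function(z, nm) {
    lay <- L[[nm]]
    a <- conv2d_fwd(z, lay$W, lay$b, lay$kh, lay$kw)
    cache[[paste0(nm, "_in")]] <<- z
    cache[[paste0(nm, "_pre")]] <<- a
    reluFwd(a)
  }
  z <- x
  pools <- list()
  blocks <- list(c("conv1_1", "conv1_2"), c("conv2_1", "conv2_2"),
                 c("conv3_1", "conv3_2", "conv3_3"),
                 c("conv4_1", "conv4_2", "conv4_3"),
                 c("conv5_1", "conv5_2", "conv5_3"))
  for (b in 1:5) {
    for (nm in blocks[[b]]) z <- convRelu(z, nm)
    pl <- maxpool2_fwd(z)
    cache[[paste0("pool", b, "_dims")]] <- dim(z)
    cache[[paste0("pool", b, "_idx")]] <- pl$idx
    z <- pl$y
    pools[[b]] <- z
  }
  z <- convRelu(z, "fc6")
  if (train && drop > 0) {
    m6 <- array(rbinom(length(z), 1, 1 - drop) / (1 - drop), dim(z))
    cache$drop6 <- m6
    z <- z * m6
  }
  z <- convRelu(z, "fc7")
  if (train && drop > 0) {
    m7 <- array(rbinom(length(z), 1, 1 - drop) / (1 - drop), dim(z))
    cache$drop7 <- m7
    z <- z * m7
  }
  sc <- L$score
  cache$score_in <- z
  u <- conv2d_fwd(z, sc$W, sc$b, 1L, 1L)
  # upsampling path with skip fusions at pool4, pool3, pool2
  taps <- list(pools[[4]], pools[[3]], pools[[2]])
  tgt <- c(net$sizes[4], net$sizes[3], net$sizes[2])
  for (k in 1:3) {
    upnm <- paste0("up", k); sknm <- paste0("skip", k)
    lay <- L[[upnm]]
    cache[[paste0(upnm, "_in")]] <- u
    full <- convtr2d_fwd(u, lay$W, lay$b, lay$k, lay$s)
    cache[[paste0(upnm, "_fulldims")]] <- dim(full)
    u <- cropCenter(full, tgt[k])
    sk <- L[[sknm]]
    cache[[paste0(sknm, "_in")]] <- taps[[k]]
    u <- u + conv2d_fwd(taps[[k]], sk$W, sk$b, 1L, 1L)
  }
  lay <- L$up4
  cache$up4_in <- u
  full <- convtr2d_fwd(u, lay$W, lay$b, lay$k, lay$s)
  cache$up4_fulldims <- dim(full)
  logits <- cropCenter(full, net$config$inputSide)
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob[, , 1], logits = logits, cache = cache)
}

# backward pass; returns gradients named like the layers
backwardCDL <- function(net, cache, dLogits) {
  L <- net$layers
  grads <- list()
  convBwd <- function(nm, dy) {
    lay <- L[[nm]]
    g <- conv2d_bwd(cache[[paste0(nm, "_in")]], lay$W, dy, lay$kh, lay$kw)
    grads[[nm]] <<- list(dW = g$dW, db = g$db)
    g$dx
  }
  convtrBwd <- function(nm, dyCropped) {
    lay <- L[[nm]]
    fd <- cache[[paste0(nm, "_fulldims")]]
    dyFull <- padToFull(dyCropped, fd[1], fd[2])
    g <- convtr2d_bwd(cache[[paste0(nm, "_in")]], lay$W, dyFull, lay$k,
                      lay$s)
    grads[[nm]] <<- list(dW = g$dW, db = g$db)
    g$dx
  }
  reluBwd <- function(nm, dy) dy * (cache[[paste0(nm, "_pre")]] > 0)

  # upsampling path: up4 back to u3, then at each fused map the gradient
  # splits into the skip branch (toward pool4/pool3/pool2) and the deeper
  # transposed-convolution branch
  du3 <- convtrBwd("up4", dLogits)
  dSkipP2 <- convBwd("skip3", du3)
  du2 <- convtrBwd("up3", du3)
  dSkipP3 <- convBwd("skip2", du2)
  du1 <- convtrBwd("up2", du2)
  dSkipP4 <- convBwd("skip1", du1)
  du0 <- convtrBwd("up1", du1)
  sc <- L$score
  g <- conv2d_bwd(cache$score_in, sc$W, du0, 1L, 1L)
  grads$score <- list(dW = g$dW, db = g$db)
  dz <- g$dx
  if (!is.null(cache$drop7)) dz <- dz * cache$drop7
  dz <- reluBwd("fc7", dz)
  dz <- convBwd("fc7", dz)
  if (!is.null(cache$drop6)) dz <- dz * cache$drop6
  dz <- reluBwd("fc6", dz)
  dz <- convBwd("fc6", dz)
  blocks <- list(c("conv1_1", "conv1_2"), c("conv2_1", "conv2_2"),
                 c("conv3_1", "conv3_2", "conv3_3"),
                 c("conv4_1", "conv4_2", "conv4_3"),
                 c("conv5_1", "conv5_2", "conv5_3"))
  # dz is now the gradient at pool5's output; skip gradients join at the
  # pool4 / pool3 / pool2 outputs as the chain walks down
  for (b in 5:1) {
    if (b == 4L) dz <- dz + dSkipP4
    if (b == 3L) dz <- dz + dSkipP3
    if (b == 2L) dz <- dz + dSkipP2
    dims <- cache[[paste0("pool", b, "_dims")]]
    dz <- maxpool2_bwd(dz, cache[[paste0("pool", b, "_idx")]],
                       dims[1], dims[2])
    for (nm in rev(blocks[[b]])) {
      dz <- reluBwd(nm, dz)
      dz <- convBwd(nm, dz)
    }
  }
  grads
}

# tile -> network input: centered intensities in roughly [-0.5, 0.5]
tileToInput <- function(tile) {
  x <- tile@pixels / 255 - 0.5
  array(x, dim(x))
}

adamInit <- function(layers) {
  st <- list()
  for (nm in names(layers)) {
    st[[nm]] <- list(mW = layers[[nm]]$W * 0, vW = layers[[nm]]$W * 0,
                     mb = layers[[nm]]$b * 0, vb = layers[[nm]]$b * 0)
  }
  st
}

adamStep <- function(net, opt, grads, lr, l2, step) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  corr1 <- 1 - b1^step; corr2 <- 1 - b2^step
  for (nm in names(grads)) {
    lay <- net$layers[[nm]]
    rate <- if (identical(lay$lrGroup, "pretrained")) lr$pretrained else lr$new
    g <- grads[[nm]]$dW + l2 * lay$W
    opt[[nm]]$mW <- b1 * opt[[nm]]$mW + (1 - b1) * g
    opt[[nm]]$vW <- b2 * opt[[nm]]$vW + (1 - b2) * g^2
    net$layers[[nm]]$W <- lay$W - rate * (opt[[nm]]$mW / corr1) /
      (sqrt(opt[[nm]]$vW / corr2) + eps)
    gb <- grads[[nm]]$db
    opt[[nm]]$mb <- b1 * opt[[nm]]$mb + (1 - b1) * gb
    opt[[nm]]$vb <- b2 * opt[[nm]]$vb + (1 - b2) * gb^2
    net$layers[[nm]]$b <- lay$b - rate * (opt[[nm]]$mb / corr1) /
      (sqrt(opt[[nm]]$vb / corr2) + eps)
  }
  list(net = net, opt = opt)
}

accumulateGrads <- function(total, g) {
  if (is.null(total)) return(g)
  for (nm in names(g)) {
    total[[nm]]$dW <- total[[nm]]$dW + g[[nm]]$dW
    total[[nm]]$db <- total[[nm]]$db + g[[nm]]$db
  }
  total
}

scaleGrads <- function(g, f) {
  for (nm in names(g)) {
    g[[nm]]$dW <- g[[nm]]$dW * f
    g[[nm]]$db <- g[[nm]]$db * f
  }
  g
}

#' Train the CDL network
#'
#' Adam optimization of the focal loss with L2 regularization, dropout on
#' the FC-equivalent layers, on-the-fly augmentation of the training tiles,
#' plateau-based halving of the learning rates (validation loss flat for 2
#' epochs), and early stopping on validation loss with the configured
#' patience. A non-finite loss aborts with a `cdl_divergence` condition
#' carrying the state snapshot.
#'
#' @param net a network from [buildCDL()] (optionally through
#'   [transferWeights()]).
#' @param trainTiles,valTiles lists of [HistologyTile-class] objects with
#'   masks, already at the configured input side.
#' @param config the [cdlConfig()] list used to build the network.
#' @param augment logical; apply [augmentTile()] to training tiles.
#' @param verbose print per-epoch progress.
#' @return a [TrainState-class]; its `network` slot holds the trained
#'   network.
#' @export
trainCDL <- function(net, trainTiles, valTiles, config = net$config,
                     augment = TRUE, verbose = FALSE) {
  stopifnot(length(trainTiles) >= 1L, length(valTiles) >= 1L)
  alpha <- config$focalAlpha; gamma <- config$focalGamma
  lr <- list(pretrained = config$lrPretrained, new = config$lrNew)
  # many small GEMMs: BLAS threading costs more than it saves here
  prevThreads <- blas_get_threads()
  if (prevThreads > 0) {
    blas_set_threads(1L)
    on.exit(blas_set_threads(prevThreads), add = TRUE)
  }
  withSeed(config$seed + 1L, {
    opt <- adamInit(net$layers)
    history <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                          valLoss = numeric(0), valF1 = numeric(0))
    bestVal <- Inf; sinceImprove <- 0L; plateau <- 0L; step <- 0L
    bestLayers <- net$layers
    epoch <- 0L
    stoppedEarly <- FALSE
    while (epoch < config$maxEpochs) {
      epoch <- epoch + 1L
      ord <- sample.int(length(trainTiles))
      lossSum <- 0
      batchGrads <- NULL; batchN <- 0L
      for (ti in ord) {
        tile <- trainTiles[[ti]]
        if (augment) tile <- augmentTile(tile)
        x <- tileToInput(tile)
        fw <- forwardCDL(net, x, train = TRUE)
        target <- tile@mask
        loss <- focalLoss(fw$prob, target, alpha, gamma)
        if (!is.finite(loss)) {
          snapshot <- new("TrainState", epoch = epoch, bestValLoss = bestVal,
                          epochsSinceImprovement = sinceImprove,
                          history = history, network = net,
                          stoppedEarly = FALSE)
          cond <- structure(class = c("cdl_divergence", "error", "condition"),
                            list(message = "trainCDL: non-finite loss; aborting",
                                 call = sys.call(-1), state = snapshot))
          stop(cond)
        }
        lossSum <- lossSum + loss
        dLogit <- focalLossGradLogit(fw$prob, target, alpha, gamma)
        dLogits <- array(dLogit, c(dim(target), 1L))
        batchGrads <- accumulateGrads(batchGrads,
                                      backwardCDL(net, fw$cache, dLogits))
        batchN <- batchN + 1L
        if (batchN == config$batchSize || ti == ord[length(ord)]) {
          step <- step + 1L
          upd <- adamStep(net, opt, scaleGrads(batchGrads, 1 / batchN),
                          lr, config$l2, step)
          net <- upd$net; opt <- upd$opt
          batchGrads <- NULL; batchN <- 0L
        }
      }
      trainLoss <- lossSum / length(trainTiles)
      # validation
      valLoss <- 0; tp <- 0; fp <- 0; fn <- 0
      for (tile in valTiles) {
        fw <- forwardCDL(net, tileToInput(tile), train = FALSE)
        valLoss <- valLoss + focalLoss(fw$prob, tile@mask, alpha, gamma)
        pred <- fw$prob > 0.5
        tp <- tp + sum(pred & tile@mask == 1)
        fp <- fp + sum(pred & tile@mask == 0)
        fn <- fn + sum(!pred & tile@mask == 1)
      }
      valLoss <- valLoss / length(valTiles)
      valF1 <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
      history <- rbind(history, data.frame(epoch = epoch,
                                           trainLoss = trainLoss,
                                           valLoss = valLoss, valF1 = valF1))
      if (verbose)
        message(sprintf("epoch %d: train %.5f val %.5f valF1 %.3f",
                        epoch, trainLoss, valLoss, valF1))
      if (valLoss < bestVal - 1e-6) {
        bestVal <- valLoss; sinceImprove <- 0L; plateau <- 0L
        bestLayers <- net$layers
      } else {
        sinceImprove <- sinceImprove + 1L
        plateau <- plateau + 1L
        if (plateau >= 2L) {  # ReduceLROnPlateau (never revives a zero rate)
          if (lr$new > 0) lr$new <- max(lr$new * 0.5, 1e-6)
          if (lr$pretrained > 0)
            lr$pretrained <- max(lr$pretrained * 0.5, 1e-8)
          plateau <- 0L
        }
        if (sinceImprove >= config$patience) {
          stoppedEarly <- TRUE
          break
        }
      }
    }
    net$layers <- bestLayers
    net$trained <- TRUE
    new("TrainState", epoch = epoch, bestValLoss = bestVal,
        epochsSinceImprovement = sinceImprove, history = history,
        network = net, stoppedEarly = stoppedEarly)
  })
}

#' Predict a per-pixel mitosis probability map
#'
#' @param net a network from [buildCDL()] or [trainCDL()]'s `network` slot.
#' @param tile a [HistologyTile-class] at the configured input side.
#' @return H x W matrix of probabilities in \[0, 1\].
#' @export
predictSegmentation <- function(net, tile) {
  if (!isTRUE(net$trained))
    warning("predictSegmentation: network has not been trained")
  x <- tileToInput(tile)
  if (dim(x)[1] != net$config$inputSide)
    stopShape("predictSegmentation: tile side does not match the network")
  forwardCDL(net, x, train = FALSE)$prob
}

#' Extract object-level detections from a probability map
#'
#' Thresholds the map, labels connected components, drops components
#' smaller than `minArea`, and returns one detection per surviving
#' component (0-based centroid row/col, area, mean score), sorted by score
#' descending.
#'
#' @param probMap H x W matrix of probabilities in \[0, 1\].
#' @param threshold probability threshold (default 0.5).
#' @param minArea minimum component area in pixels (default 10).
#' @return data.frame with columns `row`, `col`, `area`, `score`.
#' @export
postprocessDetections <- function(probMap, threshold = 0.5, minArea = 10L) {
  stopifnot(min(probMap) >= 0, max(probMap) <= 1)
  bin <- (probMap >= threshold) + 0
  labels <- EBImage::bwlabel(bin)
  n <- max(labels)
  if (n == 0L)
    return(data.frame(row = numeric(0), col = numeric(0),
                      area = integer(0), score = numeric(0)))
  rows <- lapply(seq_len(n), function(i) {
    px <- which(labels == i, arr.ind = TRUE)
    if (nrow(px) < minArea) return(NULL)
    data.frame(row = mean(px[, 1]) - 1, col = mean(px[, 2]) - 1,
               area = nrow(px), score = mean(probMap[px]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(row = numeric(0), col = numeric(0),
                      area = integer(0), score = numeric(0)))
  out[order(-out$score), , drop = FALSE]
}

#' Save or load a network checkpoint
#'
#' Single-file archive of the named weight arrays plus the configuration
#' echo and feature-registry version.
#'
#' @param net a network list.
#' @param path checkpoint path.
#' @param registryVersion registry version string recorded alongside.
#' @return `saveCheckpoint` the path invisibly; `loadCheckpoint` the
#'   network.
#' @export
saveCheckpoint <- function(net, path, registryVersion = "1.0") {
  saveRDS(list(layers = net$layers, config = net$config, sizes = net$sizes,
               nConvLayers = net$nConvLayers,
               nFCEquivalent = net$nFCEquivalent, nSkips = net$nSkips,
               trained = net$trained, registryVersion = registryVersion),
          path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  obj <- readRDS(path)
  obj$config <- do.call(cdlConfig, obj$config[setdiff(names(obj$config),
                                                      "nSkips")])
  obj
}
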