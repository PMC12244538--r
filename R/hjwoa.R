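# Hybrid jellyfish-search + walrus-optimization wrapper feature selection.
# Continuous positions in [0,1]^d are binarized at 0.5 (ties select); subset
# fitness is the stratified cross-validated F1 of a fast regularized
# diagonal linear discriminant on the z-scored selected columns. The
# metaheuristic core minimizes 1 - F1.

#' HJWOA configuration
#'
#' Defaults follow the reported optimizer settings: population 50, 100
#' iterations, crossover rate 0.8, mutation rate 0.2, time-control threshold
#' 0.5.
#'
#' @param population population size (>= 4).
#' @param iterations maximum iterations.
#' @param crossoverRate probability that the JSO and WaOA candidates
#'   recombine by per-dimension uniform crossover (otherwise the fitter
#'   candidate is taken).
#' @param mutationRate probability that one uniformly chosen dimension of
#'   the combined candidate is resampled in \[0, 1\].
#' @param kappa JSO time-control threshold.
#' @param cvFolds stratified cross-validation folds for the fitness (>= 2).
#' @param seed integer seed (mandatory).
#' @param stagnationPatience iterations without best improvement before an
#'   early stop.
#' @param threshold binarization threshold on the continuous position.
#' @return validated configuration list of class `HJWOAConfig`.
#' @export
hjwoaConfig <- function(population = 50L, iterations = 100L,
                        crossoverRate = 0.8, mutationRate = 0.2,
                        kappa = 0.5, cvFolds = 3L, seed,
                        stagnationPatience = 15L, threshold = 0.5) {
  if (missing(seed)) stop("hjwoaConfig: seed is mandatory")
  stopifnot(population >= 4L, iterations >= 1L, cvFolds >= 2L,
            crossoverRate >= 0, crossoverRate <= 1,
            mutationRate >= 0, mutationRate <= 1,
            kappa > 0, kappa < 1, stagnationPatience >= 1L)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 crossoverRate = crossoverRate, mutationRate = mutationRate,
                 kappa = kappa, cvFolds = as.integer(cvFolds),
                 seed = as.integer(seed),
                 stagnationPatience = as.integer(stagnationPatience),
                 threshold = threshold), class = "HJWOAConfig")
}

# stratified fold assignment, deterministic given the RNG state
stratifiedFolds <- function(y, k) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# regularized diagonal linear discriminant: train on (X, y), predict labels
# for Xtest. X columns are z-scored by the caller.
diagLDAPredict <- function(X, y, Xtest) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  mu1 <- colMeans(X[y == 1L, , drop = FALSE])
  mu0 <- colMeans(X[y == 0L, , drop = FALSE])
  c1 <- sweep(X[y == 1L, , drop = FALSE], 2, mu1)
  c0 <- sweep(X[y == 0L, , drop = FALSE], 2, mu0)
  v <- (colSums(c1^2) + colSums(c0^2)) / max(1L, n1 + n0 - 2L)
  v <- v + 0.1 * mean(v) + 1e-8  # shrinkage toward the average variance
  # delta1 - delta0 > 0 => class 1
  d1 <- sweep(Xtest, 2, mu1); d0 <- sweep(Xtest, 2, mu0)
  score <- rowSums(sweep(d0^2 - d1^2, 2, 2 * v, `/`)) +
    log(n1 / max(1L, n0))
  as.integer(score > 0)
}

f1FromPredictions <- function(pred, truth) {
  tp <- sum(pred == 1L & truth == 1L)
  fp <- sum(pred == 1L & truth == 0L)
  fn <- sum(pred == 0L & truth == 1L)
  if (tp == 0L) return(0)
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Cross-validated F1 of a feature subset
#'
#' Z-scores the selected columns per training fold, runs stratified k-fold
#' cross-validation of the internal regularized diagonal linear
#' discriminant, pools the validation predictions and returns
#' F1 = 2PR/(P + R). An empty mask scores 0. When a cache environment is
#' supplied, results are memoized by mask and repeated evaluations perform
#' no classifier work.
#'
#' @param mask 0/1 (or logical) vector over the columns of `X`.
#' @param X numeric n x d feature matrix, all finite.
#' @param y 0/1 labels with both classes present; `n >= 2 * cvFolds`.
#' @param config an [hjwoaConfig()] list.
#' @param folds optional precomputed fold assignment (length n).
#' @param cache optional environment used as a fitness memo; its `calls`
#'   entry counts actual classifier evaluations.
#' @return F1 in \[0, 1\].
#' @export
subsetFitness <- function(mask, X, y, config, folds = NULL, cache = NULL) {
  mask <- as.integer(as.logical(mask))
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("subsetFitness: labels must contain both classes")
  stopifnot(all(is.finite(X)), length(y) == nrow(X),
            nrow(X) >= 2L * config$cvFolds)
  if (!any(mask == 1L)) return(0)
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(which(mask == 1L), collapse = ",")
    hit <- cache$memo[[key]]
    if (!is.null(hit)) return(hit)
  }
  if (is.null(folds)) folds <- withSeed(config$seed, stratifiedFolds(y, config$cvFolds))
  Xs <- X[, mask == 1L, drop = FALSE]
  # one-pass sufficient statistics per (fold, class) group; the z-scored
  # diagonal discriminant is linear in x, so each fold is a single
  # matrix-vector product (algebraically identical to diagLDAPredict on
  # z-scored columns)
  g <- (folds - 1L) * 2L + y + 1L
  cnt <- tabulate(g, 2L * config$cvFolds)
  S <- rowsum(Xs, g)
  Q <- rowsum(Xs * Xs, g)
  pred <- integer(length(y))
  for (k in seq_len(config$cvFolds)) {
    g0 <- (k - 1L) * 2L + 1L; g1 <- g0 + 1L
    trIdx <- setdiff(seq_len(2L * config$cvFolds), c(g0, g1))
    ev <- trIdx %% 2L == 1L
    n0 <- sum(cnt[trIdx[ev]]); n1 <- sum(cnt[trIdx[!ev]])
    S0 <- colSums(S[trIdx[ev], , drop = FALSE])
    S1 <- colSums(S[trIdx[!ev], , drop = FALSE])
    Q0 <- colSums(Q[trIdx[ev], , drop = FALSE])
    Q1 <- colSums(Q[trIdx[!ev], , drop = FALSE])
    n <- n0 + n1
    m <- (S0 + S1) / n
    s2 <- pmax((Q0 + Q1) / n - m^2, 0)
    s <- sqrt(s2); s[s < 1e-9] <- 1
    mu0 <- (S0 / n0 - m) / s
    mu1 <- (S1 / n1 - m) / s
    v0 <- pmax(Q0 / n0 - (S0 / n0)^2, 0) / s^2
    v1 <- pmax(Q1 / n1 - (S1 / n1)^2, 0) / s^2
    v <- (n0 * v0 + n1 * v1) / max(1L, n - 2L)
    v <- v + 0.1 * mean(v) + 1e-8
    w <- (mu1 - mu0) / v
    c0 <- -sum((mu1^2 - mu0^2) / (2 * v)) + log(n1 / max(1L, n0))
    te <- folds == k
    score <- drop(Xs[te, , drop = FALSE] %*% (w / s)) - sum(m * w / s) + c0
    pred[te] <- as.integer(score > 0)
  }
  f1 <- f1FromPredictions(pred, y)
  if (!is.null(cache)) {
    cache$memo[[key]] <- f1
    cache$calls <- (cache$calls %||% 0L) + 1L
  }
  f1
}

# position -> mask at the configured threshold (ties select the feature)
positionToMask <- function(position, threshold = 0.5) {
  as.integer(position >= threshold)
}

# TRUE if mask a beats mask b at equal fitness: fewer features, then
# lexicographically smaller
maskPreferred <- function(a, b) {
  if (sum(a) != sum(b)) return(sum(a) < sum(b))
  diffIdx <- which(a != b)
  if (!length(diffIdx)) return(FALSE)
  a[diffIdx[1]] < b[diffIdx[1]]
}

#' Run hybrid JSO + WaOA wrapper feature selection
#'
#' Each iteration every agent produces a JSO candidate (ocean-current /
#' passive / active move) and a WaOA candidate (feeding, migration and
#' escape phases cycling across iterations). With probability
#' `crossoverRate` the two recombine by per-dimension uniform crossover;
#' otherwise the fitter candidate is taken. With probability `mutationRate`
#' one uniformly chosen dimension is resampled in \[0, 1\]. The result is
#' accepted greedily against the incumbent. The best mask ever evaluated is
#' returned; the run stops after `iterations` or once the best fitness has
#' not improved for `stagnationPatience` iterations.
#'
#' @param X numeric n x d feature matrix.
#' @param y 0/1 labels.
#' @param registry optional [FeatureRegistry-class] used for category
#'   shares in the result (must have d slots).
#' @param config an [hjwoaConfig()] list.
#' @return a [SelectionResult-class].
#' @export
#' @examples
#' tab <- genFeatureTable(tableGenParams(nSamples = 60, d = 8,
#'   nInformative = 2, effectSize = 2, seed = 1))
#' res <- hjwoaRun(tab$X, tab$y,
#'   config = hjwoaConfig(population = 8, iterations = 5, seed = 1))
#' selectionFitness(res)
hjwoaRun <- function(X, y, registry = NULL, config) {
  stopifnot(inherits(config, "HJWOAConfig"))
  d <- ncol(X)
  y <- as.integer(y)
  cache <- new.env(parent = emptyenv())
  cache$memo <- new.env(parent = emptyenv())
  withSeed(config$seed, {
    folds <- stratifiedFolds(y, config$cvFolds)
    evalPosition <- function(pos) {
      subsetFitness(positionToMask(pos, config$threshold), X, y, config,
                    folds = folds, cache = cache)
    }
    bounds <- searchBounds(0, 1, d = d)
    jp <- jsoParams(kappa = config$kappa,
                    q0 = { q <- runif(1, 0.05, 0.95)
                           while (min(abs(q - c(0.25, 0.5, 0.75))) < 1e-3)
                             q <- runif(1, 0.05, 0.95)
                           q })
    n <- config$population
    P <- chaoticInit(n, bounds, jp)
    fit <- apply(P, 1, evalPosition)          # F1 per agent (maximized)
    bestIdx <- which.max(fit)
    bestMask <- positionToMask(P[bestIdx, ], config$threshold)
    bestF1 <- fit[bestIdx]
    bestPos <- P[bestIdx, ]
    history <- numeric(0)
    sinceImprove <- 0L
    waoaPhase <- 0L
    for (t in seq_len(config$iterations)) {
      lambdaC <- colMeans(P)
      improvedThisIter <- FALSE
      for (j in seq_len(n)) {
        Y <- P[j, ]
        # --- JSO candidate ---
        tcf <- timeControl(t, config$iterations)
        if (tcf >= config$kappa) {
          R <- runif(d)
          candA <- Y + R * (bestPos - 3 * R * lambdaC)
        } else if (runif(1) > 1 - tcf) {
          candA <- Y + runif(d) * 0.1
        } else {
          i <- sampleOne(setdiff(seq_len(n), j))
          R <- runif(d)
          candA <- if (fit[j] <= fit[i]) Y + R * (P[i, ] - Y)
                   else Y + R * (Y - P[i, ])
        }
        candA <- wrapBounds(candA, bounds@lb, bounds@ub)
        # --- WaOA candidate (phases cycle across iterations) ---
        phase <- waoaPhase %% 3L
        if (phase == 0L) {
          RI <- sample(1:2, d, replace = TRUE)
          candB <- Y + (bestPos - RI * Y) * runif(d)
        } else if (phase == 1L) {
          l <- sampleOne(setdiff(seq_len(n), j))
          RI <- sample(1:2, d, replace = TRUE)
          rand <- runif(d)
          candB <- if (fit[l] > fit[j]) Y + (P[l, ] - RI * Y) * rand
                   else Y + (Y - P[l, ]) * rand
        } else {
          half <- 1 / (2 * t)
          candB <- Y + (-half + 2 * half * runif(d))
        }
        candB <- clampRange(candB, 0, 1)
        # --- hybridization ---
        if (runif(1) < config$crossoverRate) {
          pick <- runif(d) < 0.5
          child <- ifelse(pick, candA, candB)
        } else {
          child <- if (evalPosition(candA) >= evalPosition(candB)) candA
                   else candB
        }
        if (runif(1) < config$mutationRate)
          child[sample.int(d, 1L)] <- runif(1)
        f1 <- evalPosition(child)
        if (f1 > fit[j]) {
          P[j, ] <- child
          fit[j] <- f1
        }
        childMask <- positionToMask(child, config$threshold)
        if (f1 > bestF1 ||
            (f1 == bestF1 && maskPreferred(childMask, bestMask))) {
          if (f1 > bestF1) improvedThisIter <- TRUE
          bestF1 <- f1
          bestMask <- childMask
          bestPos <- child
        }
      }
      waoaPhase <- waoaPhase + 1L
      history <- c(history, bestF1)
      sinceImprove <- if (improvedThisIter) 0L else sinceImprove + 1L
      if (sinceImprove >= config$stagnationPatience) break
    }
    shares <- categoryShares(bestMask, registry)
    new("SelectionResult", mask = bestMask, fitness = bestF1,
        history = history, categoryShares = shares,
        nSelected = sum(bestMask), seed = config$seed,
        config = unclass(config))
  })
}

categoryShares <- function(mask, registry) {
  cats <- c("texture", "shape", "color")
  if (is.null(registry) || sum(mask) == 0L)
    return(setNames(numeric(3), cats))
  sel <- registry@categories[mask == 1L]
  setNames(vapply(cats, function(cc) mean(sel == cc), numeric(1)), cats)
}

#' Summarize a selection result
#'
#' Reports the number of selected features, per-category shares, and
#' informational flags for whether the count falls in the reported 35-50
#' range and the shares inside the reported category bands (these are
#' diagnostics, never enforced).
#'
#' @param result a [SelectionResult-class].
#' @param registry a [FeatureRegistry-class].
#' @return a list report.
#' @export
selectionReport <- function(result, registry) {
  stopifnot(is(result, "SelectionResult"), is(registry, "FeatureRegistry"))
  shares <- categoryShares(result@mask, registry)
  list(nSelected = result@nSelected,
       fitness = result@fitness,
       categoryShares = as.list(shares),
       selectedSlots = registry@slotNames[result@mask == 1L],
       flags = list(
         nSelectedInReportedRange = result@nSelected >= 35L &&
           result@nSelected <= 50L,
         textureShareInBand = shares["texture"] >= 0.5 &&
           shares["texture"] <= 0.6,
         shapeShareInBand = shares["shape"] >= 0.25 &&
           shares["shape"] <= 0.30,
         colorShareInBand = shares["color"] >= 0.10 &&
           shares["color"] <= 0.15,
         emptySelection = result@nSelected == 0L))
}

#' Write a selection result to JSON
#'
#' @param result a [SelectionResult-class].
#' @param registry a [FeatureRegistry-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSelectionJSON <- function(result, registry, path) {
  rep <- selectionReport(result, registry)
  jsonlite::write_json(list(
    mask = result@mask, slotNames = registry@slotNames,
    fitness = result@fitness, nSelected = result@nSelected,
    categoryShares = rep$categoryShares, flags = rep$flags,
    history = result@history, seed = result@seed,
    config = result@config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Exhaustive subset-selection oracle (small d)
#'
#' Enumerates all 2^d - 1 non-empty masks and returns the optimum under the
#' same fitness as [hjwoaRun()], with the same tie-breaking (fewer features,
#' then lexicographically smaller). Practical only for d <= 15.
#'
#' @inheritParams hjwoaRun
#' @return list with `mask` and `fitness`.
#' @export
exhaustiveSelection <- function(X, y, config) {
  d <- ncol(X)
  stopifnot(d <= 20L)
  y <- as.integer(y)
  folds <- withSeed(config$seed, stratifiedFolds(y, config$cvFolds))
  bestF1 <- -Inf; bestMask <- NULL
  for (code in seq_len(2^d - 1L)) {
    mask <- as.integer(bitwAnd(bitwShiftR(code, 0:(d - 1L)), 1L))
    f1 <- subsetFitness(mask, X, y, config, folds = folds)
    if (f1 > bestF1 || (f1 == bestF1 && maskPreferred(mask, bestMask))) {
      bestF1 <- f1
      bestMask <- mask
    }
  }
  list(mask = bestMask, fitness = bestF1)
}
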