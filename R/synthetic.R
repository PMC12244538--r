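# Seeded synthetic-data generators: H&E-like tiles with known mitosis masks,
# labeled feature tables with a known informative subset, and standard
# benchmark objectives for the optimizers. These define the package's entire
# test substrate; no external images are required anywhere.

#' Tile generator parameters
#'
#' @param side tile side length in pixels.
#' @param nNuclei total number of nuclei to render.
#' @param nMitotic number of mitotic figures among them (`<= nNuclei`).
#' @param stainPerturbation angular jitter (radians, sd) applied to the
#'   default H&E stain vectors per tile; must be < 0.5.
#' @param noiseSd additive intensity noise sd (0-255 scale).
#' @param difficulty `"easy"` (high contrast, low jitter, well-separated
#'   objects) or `"hard"` (lower contrast, crowding allowed).
#' @param seed integer seed.
#' @param stainSeed optional separate seed for the stain-vector jitter;
#'   defaults to `seed`. Two tiles sharing `seed` but differing in
#'   `stainSeed` render the same scene under different stains.
#' @return validated parameter list of class `TileGenParams`.
#' @export
tileGenParams <- function(side = 227L, nNuclei = 30L, nMitotic = 4L,
                          stainPerturbation = 0.05, noiseSd = 2,
                          difficulty = c("easy", "hard"), seed,
                          stainSeed = NULL) {
  difficulty <- match.arg(difficulty)
  if (missing(seed)) stop("tileGenParams: seed is mandatory")
  stopifnot(side >= 32L, nMitotic <= nNuclei, nMitotic >= 0L,
            stainPerturbation >= 0, stainPerturbation < 0.5, noiseSd >= 0)
  structure(list(side = as.integer(side), nNuclei = as.integer(nNuclei),
                 nMitotic = as.integer(nMitotic),
                 stainPerturbation = stainPerturbation, noiseSd = noiseSd,
                 difficulty = difficulty, seed = as.integer(seed),
                 stainSeed = as.integer(stainSeed %||% seed)),
            class = "TileGenParams")
}

#' Feature-table generator parameters
#'
#' @param nSamples number of rows.
#' @param d number of features (default 150).
#' @param nInformative number of class-separating columns.
#' @param effectSize standardized between-class mean shift of informative
#'   columns; each informative column's theoretical AUC is
#'   `pnorm(effectSize / sqrt(2))`.
#' @param classBalance proportion of class-1 rows (exact allocation).
#' @param correlation equicorrelation among nuisance columns, in \[0, 1).
#' @param seed integer seed.
#' @return validated parameter list of class `TableGenParams`.
#' @export
tableGenParams <- function(nSamples, d = 150L, nInformative, effectSize,
                           classBalance = 0.5, correlation = 0, seed) {
  if (missing(seed)) stop("tableGenParams: seed is mandatory")
  stopifnot(nInformative <= d, effectSize >= 0, classBalance > 0,
            classBalance < 1, correlation >= 0, correlation < 1)
  structure(list(nSamples = as.integer(nSamples), d = as.integer(d),
                 nInformative = as.integer(nInformative),
                 effectSize = effectSize, classBalance = classBalance,
                 correlation = correlation, seed = as.integer(seed)),
            class = "TableGenParams")
}

# smooth random field on [lo, hi]: coarse uniform grid upsampled bilinearly
smoothField <- function(side, coarse, lo, hi) {
  g <- matrix(runif(coarse^2, lo, hi), coarse, coarse)
  as.matrix(EBImage::resize(EBImage::Image(g), w = side, h = side))
}

# angular jitter of a unit stain vector: rotate by N(0, sigma) radians
# toward a random orthogonal direction, keep non-negative, renormalize
jitterStainVector <- function(v, sigma) {
  if (sigma <= 0) return(v)
  u <- rnorm(3)
  u <- u - sum(u * v) * v
  nu <- sqrt(sum(u^2))
  if (nu < 1e-12) return(v)
  u <- u / nu
  theta <- rnorm(1, 0, sigma)
  w <- pmax(cos(theta) * v + sin(theta) * u, 0)
  w / sqrt(sum(w^2))
}

#' Generate a synthetic H&E-like tile with a known mitosis mask
#'
#' Renders an eosin-tinted background texture, hematoxylin-tinted elliptical
#' nuclei and darker, irregular (star-convex perturbed) mitotic chromatin
#' figures, composes them through the optical-density stain model with
#' per-tile jittered stain vectors, and adds intensity noise. The mask marks
#' exactly the mitotic figures; per-object centers and flags are attached as
#' the `"objects"` attribute (a data.frame).
#'
#' @param params a [tileGenParams()] list.
#' @return a [HistologyTile-class] with ground-truth mask.
#' @export
#' @examples
#' tile <- genHETile(tileGenParams(side = 64, nNuclei = 10, nMitotic = 2,
#'                                 seed = 3))
#' sum(tileMask(tile))
genHETile <- function(params) {
  stopifnot(inherits(params, "TileGenParams"))
  M <- withSeed(params$stainSeed, {
    M0 <- defaultStainMatrix()
    sigma <- params$stainPerturbation *
      (if (params$difficulty == "easy") 1 else 1.6)
    rbind(jitterStainVector(M0[1, ], sigma),
          jitterStainVector(M0[2, ], sigma))
  })
  withSeed(params$seed, {
    side <- params$side
    easy <- params$difficulty == "easy"

    # concentration fields
    CE <- smoothField(side, 8L, 0.15, if (easy) 0.30 else 0.45)
    CH <- smoothField(side, 8L, 0.01, 0.04)
    mask <- matrix(0, side, side)

    rBase <- max(4, side / 28)
    sepFactor <- if (easy) 2.4 else 1.3
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    margin <- ceiling(rBase * 1.8) + 1
    for (i in seq_len(params$nNuclei)) {
      placed <- FALSE
      isMit <- i <= params$nMitotic
      for (try in seq_len(400L)) {
        r0 <- rBase * runif(1, 0.8, 1.2)
        ctr <- runif(2, margin, side - margin)
        if (nrow(centers)) {
          dists <- sqrt(rowSums(sweep(centers, 2, ctr)^2))
          prevMit <- seq_len(nrow(centers)) <= params$nMitotic
          # mitotic figures must never touch anything (mask components stay
          # distinct); normal nuclei may crowd per difficulty
          need <- ifelse(prevMit | isMit, 2.8 * rBase, sepFactor * rBase)
          if (any(dists < need)) next
        }
        centers <- rbind(centers, ctr)
        radii <- c(radii, r0)
        placed <- TRUE
        break
      }
      if (!placed)
        stop("genHETile: overcrowding - could not place object ", i,
             " without overlap; reduce nNuclei or increase side")
    }

    objects <- data.frame(row = centers[, 1], col = centers[, 2],
                          radius = radii,
                          mitotic = seq_len(params$nNuclei) <=
                            params$nMitotic)
    for (i in seq_len(params$nNuclei)) {
      mitotic <- objects$mitotic[i]
      r0 <- radii[i]
      ctr <- centers[i, ]
      bb <- ceiling(r0 * 1.8)
      rows <- max(1, floor(ctr[1] - bb)):min(side, ceiling(ctr[1] + bb))
      cols <- max(1, floor(ctr[2] - bb)):min(side, ceiling(ctr[2] + bb))
      dx <- outer(rows - ctr[1], rep(1, length(cols)))
      dy <- outer(rep(1, length(rows)), cols - ctr[2])
      if (mitotic) {
        # star-convex radial perturbation of the boundary
        phi <- atan2(dy, dx)
        rad <- r0 * (1 + Reduce(`+`, lapply(2:5, function(k)
          rnorm(1, 0, 0.10) * cos(k * phi + runif(1, 0, 2 * pi)))))
        inside <- sqrt(dx^2 + dy^2) <= pmax(rad, 0.35 * r0)
        conc <- if (easy) runif(1, 1.35, 1.65) else runif(1, 0.95, 1.20)
      } else {
        th <- runif(1, 0, pi)
        b <- r0 * runif(1, 0.6, 0.95)
        xr <- dx * cos(th) + dy * sin(th)
        yr <- -dx * sin(th) + dy * cos(th)
        inside <- (xr / r0)^2 + (yr / b)^2 <= 1
        conc <- if (easy) runif(1, 0.45, 0.62) else runif(1, 0.55, 0.85)
      }
      texture <- 1 + 0.08 * matrix(rnorm(length(inside)), nrow(inside))
      sub <- CH[rows, cols]
      sub[inside] <- pmax(sub[inside], conc * texture[inside])
      CH[rows, cols] <- sub
      if (mitotic) {
        msub <- mask[rows, cols]
        msub[inside] <- 1
        mask[rows, cols] <- msub
      }
    }

    od <- array(0, c(side, side, 3L))
    for (ch in 1:3) od[, , ch] <- CH * M[1, ch] + CE * M[2, ch]
    px <- 255 * 10^(-od)
    if (params$noiseSd > 0)
      px <- px + array(rnorm(length(px), 0, params$noiseSd), dim(px))
    tile <- histologyTile(array(clampRange(round(px), 0, 255), dim(px)),
                          mask = mask, id = sprintf("synth-%d", params$seed))
    attr(tile, "objects") <- objects
    attr(tile, "stainMatrix") <- M
    tile
  })
}

#' Generate a labeled feature table with a known informative subset
#'
#' Class labels are allocated exactly (`round(nSamples * classBalance)` ones).
#' Informative columns get a standardized between-class mean shift of
#' `effectSize`; nuisance columns have zero shift and pairwise
#' equicorrelation `correlation` (single shared factor).
#'
#' @param params a [tableGenParams()] list.
#' @return list with `X` (n x d matrix with registry-style column names),
#'   `y` (0/1 integer vector) and `informative` (column indices).
#' @export
#' @examples
#' tab <- genFeatureTable(tableGenParams(nSamples = 100, d = 12,
#'   nInformative = 4, effectSize = 2, seed = 1))
#' tab$informative
genFeatureTable <- function(params) {
  stopifnot(inherits(params, "TableGenParams"))
  withSeed(params$seed, {
    n <- params$nSamples; d <- params$d
    n1 <- round(n * params$classBalance)
    y <- sample(c(rep(1L, n1), rep(0L, n - n1)))
    informative <- sort(sample.int(d, params$nInformative))
    rho <- params$correlation
    shared <- rnorm(n)
    X <- matrix(rnorm(n * d), n, d)
    if (rho > 0) {
      nuis <- setdiff(seq_len(d), informative)
      X[, nuis] <- sqrt(rho) * shared + sqrt(1 - rho) * X[, nuis]
    }
    X[, informative] <- X[, informative] + params$effectSize * y
    colnames(X) <- sprintf("f%03d", seq_len(d))
    list(X = X, y = y, informative = informative)
  })
}

#' Standard benchmark objectives for the optimizers
#'
#' @param name one of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @param d dimension.
#' @return list with `fn` (objective), `optimum` (location) and
#'   `optimumValue`.
#' @export
#' @examples
#' benchmarkObjective("sphere", 5)$fn(rep(1, 5))
benchmarkObjective <- function(name = c("sphere", "rastrigin", "rosenbrock"),
                               d) {
  name <- match.arg(name)
  stopifnot(d >= 1)
  switch(name,
    sphere = list(fn = function(x) sum(x^2),
                  optimum = rep(0, d), optimumValue = 0),
    rastrigin = list(
      fn = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
      optimum = rep(0, d), optimumValue = 0),
    rosenbrock = list(
      fn = function(x) {
        if (length(x) < 2) return((1 - x)^2)
        sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
      },
      optimum = rep(1, d), optimumValue = 0))
}
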