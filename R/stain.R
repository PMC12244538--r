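# Optical-density stain separation, reference normalization, preprocessing
# and dataset splitting.
#
# Stains combine approximately linearly in optical density (OD), so a tile is
# modelled as OD = C %*% M where M (2 x 3) holds the unit-norm H and E stain
# vectors and C (n x 2) the per-pixel concentrations. Normalization estimates
# C under the source tile's stain matrix, rescales each stain by the
# reference's robust concentration maxima, and re-renders through the
# reference matrix.

# Published H&E OD vectors (Ruifrok-style defaults), rows unit-normalized.
defaultStainMatrix <- function() {
  M <- rbind(h = c(0.650, 0.704, 0.286),
             e = c(0.072, 0.990, 0.105))
  M / sqrt(rowSums(M^2))
}

OD_EPS <- 1 / 255 # inside the log, avoids log(0)

#' Convert an RGB tile to optical density
#'
#' OD = -log10((pixel + 1/255) / background) per channel, so white background
#' maps to (near) zero and darker pixels to larger OD.
#'
#' @param tile a [HistologyTile-class] or an H x W x 3 array in \[0, 255\].
#' @param background background intensity (default 255).
#' @return H x W x 3 numeric optical-density array.
#' @seealso [odToRGB()] for the inverse.
#' @export
#' @examples
#' od <- rgbToOD(histologyTile(array(128, c(4, 4, 3))))
rgbToOD <- function(tile, background = 255) {
  px <- if (is(tile, "HistologyTile")) tile@pixels else tile
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stopShape("rgbToOD: input must have exactly 3 channels")
  pmax(-log10((px + OD_EPS) / background), 0)
}

#' Convert optical density back to RGB
#'
#' @param od H x W x 3 optical-density array.
#' @param background background intensity (default 255).
#' @return H x W x 3 array of rounded intensities clamped to \[0, 255\].
#' @export
odToRGB <- function(od, background = 255) {
  px <- background * 10^(-od) - OD_EPS
  array(clampRange(round(px), 0, 255), dim = dim(od))
}

#' Estimate an H&E stain profile from a reference tile
#'
#' Data-driven stain estimation: tissue pixels (OD magnitude above `beta`)
#' are projected onto the top-2 principal plane of their OD scatter; the
#' 1st/99th-percentile angular extremes define the two stain directions,
#' which are sign-corrected, clipped non-negative and unit-normalized. The
#' row with the larger red-channel OD is labelled hematoxylin. Concentration
#' scales are the per-stain 99th percentiles.
#'
#' @param reference a [HistologyTile-class].
#' @param beta OD magnitude below which a pixel counts as background.
#' @param minTissue minimum tissue fraction; below it the reference is
#'   rejected as degenerate.
#' @param fallbackDefault if `TRUE`, a chroma-free (grayscale) reference
#'   falls back to the published default stain vectors instead of erroring.
#' @return a [StainProfile-class].
#' @export
#' @examples
#' tile <- genHETile(tileGenParams(side = 64, nNuclei = 12, nMitotic = 2,
#'                                 seed = 1))
#' estimateStainProfile(tile)
estimateStainProfile <- function(reference, beta = 0.15, minTissue = 0.05,
                                 fallbackDefault = FALSE) {
  od <- rgbToOD(reference)
  odm <- matrix(od, ncol = 3L)
  mag <- sqrt(rowSums(odm^2))
  tissue <- odm[mag > beta, , drop = FALSE]
  if (nrow(tissue) / nrow(odm) < minTissue)
    stop("estimateStainProfile: degenerate reference (background fraction ",
         sprintf("%.2f", 1 - nrow(tissue) / nrow(odm)), " exceeds threshold)")
  ctr <- colMeans(tissue)
  ev <- eigen(crossprod(sweep(tissue, 2, ctr)), symmetric = TRUE)
  # chroma check: without two distinct stain directions the angular spread
  # of the projected cloud collapses
  V <- ev$vectors[, 1:2, drop = FALSE]
  proj <- tissue %*% V
  phi <- atan2(proj[, 2], proj[, 1])
  if (ev$values[2] / max(ev$values[1], 1e-12) < 1e-4 ||
      diff(range(phi)) < 1e-3) {
    if (fallbackDefault) {
      M <- defaultStainMatrix()
      sc <- concentrationScales(odm, M)
      return(new("StainProfile", stainMatrix = M, concentrationScale = sc))
    }
    stop("estimateStainProfile: no stain direction identifiable ",
         "(chroma-free reference); set fallbackDefault = TRUE to use the ",
         "published default vectors")
  }
  qs <- quantile(phi, c(0.01, 0.99), names = FALSE)
  dirs <- rbind(as.vector(V %*% c(cos(qs[1]), sin(qs[1]))),
                as.vector(V %*% c(cos(qs[2]), sin(qs[2]))))
  # stain vectors absorb: flip each so its dominant mass is positive
  for (i in 1:2) if (sum(dirs[i, ]) < 0) dirs[i, ] <- -dirs[i, ]
  dirs <- pmax(dirs, 0)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  # hematoxylin absorbs red strongly; eosin barely
  if (dirs[1, 1] < dirs[2, 1]) dirs <- dirs[2:1, , drop = FALSE]
  sc <- concentrationScales(odm, dirs)
  new("StainProfile", stainMatrix = dirs, concentrationScale = sc)
}

# robust per-stain concentration maxima (99th percentile of least-squares
# concentrations)
concentrationScales <- function(odm, M) {
  C <- odConcentrations(odm, M)
  sc <- apply(C, 2, function(x) quantile(pmax(x, 0), 0.99, names = FALSE))
  pmax(sc, 1e-6)
}

# least-squares per-pixel concentrations: OD (n x 3) ~ C (n x 2) %*% M (2 x 3)
odConcentrations <- function(odm, M) {
  odm %*% t(M) %*% solve(M %*% t(M))
}

#' Normalize a tile's staining to a reference profile
#'
#' Estimates the tile's own stain matrix and concentrations, rescales each
#' stain so its robust maximum matches the reference's, and re-renders the
#' tile through the reference stain matrix. If the tile's own stain estimate
#' fails (near-blank or chroma-free tile), the published default stain
#' matrix is used instead and a message is logged.
#'
#' @param tile a [HistologyTile-class].
#' @param profile the reference [StainProfile-class].
#' @return a [HistologyTile-class] with the same id, mask and dtype/range.
#' @export
normalizeToReference <- function(tile, profile) {
  stopifnot(is(tile, "HistologyTile"), is(profile, "StainProfile"))
  validObject(profile)
  src <- tryCatch(
    estimateStainProfile(tile, fallbackDefault = TRUE),
    error = function(e) {
      message("normalizeToReference: falling back to default stain matrix (",
              conditionMessage(e), ")")
      M <- defaultStainMatrix()
      odm <- matrix(rgbToOD(tile), ncol = 3L)
      new("StainProfile", stainMatrix = M,
          concentrationScale = concentrationScales(odm, M))
    })
  od <- rgbToOD(tile)
  dm <- dim(od)
  C <- odConcentrations(matrix(od, ncol = 3L), src@stainMatrix)
  # a stain that is essentially absent from the source has nothing to
  # rescale; leaving its ratio at 1 keeps blank tiles blank
  ratio <- profile@concentrationScale / src@concentrationScale
  ratio[src@concentrationScale < 0.02] <- 1
  C <- sweep(C, 2, ratio, `*`)
  odNew <- C %*% profile@stainMatrix
  out <- odToRGB(array(odNew, dim = dm), background = profile@backgroundIntensity[1])
  histologyTile(out, mask = tile@mask, id = tile@id, splitTag = tile@splitTag)
}

#' Pick a representative reference tile from a corpus
#'
#' Convenience helper: selects the tile whose OD-chroma histogram is closest
#' (L1) to the elementwise median histogram of the corpus.
#'
#' @param tiles list of [HistologyTile-class] objects.
#' @param bins number of angular histogram bins.
#' @return the selected tile.
#' @export
selectReferenceTile <- function(tiles, bins = 24) {
  stopifnot(length(tiles) >= 1L)
  hists <- vapply(tiles, function(tl) {
    odm <- matrix(rgbToOD(tl), ncol = 3L)
    keep <- sqrt(rowSums(odm^2)) > 0.15
    if (!any(keep)) return(rep(1 / bins, bins))
    phi <- atan2(odm[keep, 2], odm[keep, 1])
    h <- tabulate(pmin(bins, 1L + floor((phi + pi) / (2 * pi) * bins)), bins)
    h / sum(h)
  }, numeric(bins))
  med <- apply(hists, 1, median)
  tiles[[which.min(colSums(abs(hists - med)))]]
}

#' Resize and denoise a tile
#'
#' Resizes to `side` x `side` (bilinear; mask by nearest neighbour, kept
#' binary) and applies a per-channel median filter.
#'
#' @param tile a [HistologyTile-class].
#' @param side output side length in pixels (default 227).
#' @param medianKernel odd median-filter kernel width (default 3); 1 skips
#'   filtering.
#' @return the preprocessed [HistologyTile-class].
#' @export
preprocessTile <- function(tile, side = 227L, medianKernel = 3L) {
  stopifnot(is(tile, "HistologyTile"))
  side <- as.integer(side)
  if (side < 32L) stop("preprocessTile: side must be >= 32")
  if (medianKernel %% 2L != 1L || medianKernel < 1L)
    stop("preprocessTile: medianKernel must be an odd integer >= 1")
  px <- tile@pixels / 255
  d <- dim(px)
  if (d[1] != side || d[2] != side)
    px <- EBImage::resize(EBImage::Image(px, colormode = "Color"),
                          w = side, h = side)
  px <- array(px, c(side, side, 3L))
  if (medianKernel > 1L) {
    r <- (medianKernel - 1L) %/% 2L
    for (ch in 1:3)
      px[, , ch] <- as.matrix(EBImage::medianFilter(px[, , ch], size = r))
  }
  mask <- tile@mask
  if (!is.null(mask) && !all(dim(mask) == side)) {
    mask <- as.matrix(EBImage::resize(EBImage::Image(mask), w = side,
                                      h = side, filter = "none"))
    mask <- (mask > 0.5) + 0
  }
  histologyTile(array(clampRange(round(px * 255), 0, 255), c(side, side, 3L)),
                mask = mask, id = tile@id, splitTag = tile@splitTag)
}

#' Split ids into train/validation/test partitions
#'
#' Partitions are disjoint, exhaustive and reproducible from the spec's
#' seed. Split sizes follow largest-remainder rounding of the fractions;
#' stratified splits apply the same rule within each class, so per-class
#' counts deviate from exact proportionality by at most one item.
#'
#' @param ids vector of identifiers.
#' @param labels class labels aligned with `ids` (required when
#'   `spec@stratify` is `TRUE`).
#' @param spec a [SplitSpec-class].
#' @return named list with `train`, `val` and `test` id vectors.
#' @export
#' @examples
#' splitDataset(1:100, rep(0:1, 50), splitSpec(seed = 7))
splitDataset <- function(ids, labels = NULL, spec) {
  stopifnot(is(spec, "SplitSpec"))
  validObject(spec)
  n <- length(ids)
  if (spec@stratify) {
    if (is.null(labels) || length(labels) != n)
      stop("splitDataset: stratified splits need labels aligned with ids")
    nSplits <- sum(spec@fractions > 0)
    counts <- table(labels)
    if (any(counts < nSplits))
      stop("splitDataset: stratification error - class(es) ",
           paste(names(counts)[counts < nSplits], collapse = ", "),
           " have fewer members than splits")
  }
  withSeed(spec@seed, {
    parts <- list(train = ids[0], val = ids[0], test = ids[0])
    groups <- if (spec@stratify) split(seq_len(n), labels) else list(seq_len(n))
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      g <- g[sample.int(length(g))]
      sizes <- largestRemainder(length(g), spec@fractions, tieOffset = gi - 1L)
      cuts <- cumsum(sizes)
      parts$train <- c(parts$train, ids[g[seq_len(sizes[1])]])
      if (sizes[2] > 0)
        parts$val <- c(parts$val, ids[g[(cuts[1] + 1):cuts[2]]])
      if (sizes[3] > 0)
        parts$test <- c(parts$test, ids[g[(cuts[2] + 1):cuts[3]]])
    }
    parts
  })
}

# integer allocation of n by fractions, largest remainder; remainder ties
# are broken by an index rotated per group so stratified classes spread
# their spare items over different splits instead of piling on one
largestRemainder <- function(n, fractions, tieOffset = 0L) {
  raw <- n * fractions
  base <- floor(raw + 1e-9)
  rem <- n - sum(base)
  if (rem > 0) {
    k <- length(fractions)
    pref <- (seq_len(k) - 1L + tieOffset) %% k
    order_idx <- order(-(raw - base), pref)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Read and write tiles as PNG
#'
#' `readTilePNG` loads an 8-bit RGB PNG into a [HistologyTile-class];
#' `writeTilePNG` writes a tile (and optionally its mask) back out.
#'
#' @param path file path.
#' @param id tile identifier (defaults to the file name).
#' @return `readTilePNG` a [HistologyTile-class]; `writeTilePNG` the path,
#'   invisibly.
#' @export
readTilePNG <- function(path, id = basename(path)) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  histologyTile(array(round(px * 255), dim = dim(px)[c(1, 2, 3)]), id = id)
}

#' @rdname readTilePNG
#' @param tile a [HistologyTile-class].
#' @param maskPath optional path for the binary mask PNG.
#' @export
writeTilePNG <- function(tile, path, maskPath = NULL) {
  png::writePNG(tile@pixels / 255, path)
  if (!is.null(maskPath) && !is.null(tile@mask))
    png::writePNG(tile@mask, maskPath)
  invisible(path)
}

#' @rdname readTilePNG
#' @export
readTileTIFF <- function(path, id = basename(path)) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  histologyTile(array(round(px * 255), dim = dim(px)), id = id)
}
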