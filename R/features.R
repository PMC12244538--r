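# The fixed 150-slot feature bank: local directional pattern (LDP) and local
# frequency pattern (LFP) texture histograms, connected-component shape
# descriptors, and RGB/HSV color statistics.

# The 8 Kirsch compass masks, in the fixed order E, NE, N, NW, W, SW, S, SE.
# Responses are cross-correlations (sum of mask * neighborhood).
kirschMasks <- function() {
  list(
    E  = rbind(c(-3, -3, 5), c(-3, 0, 5), c(-3, -3, 5)),
    NE = rbind(c(-3, 5, 5), c(-3, 0, 5), c(-3, -3, -3)),
    N  = rbind(c(5, 5, 5), c(-3, 0, -3), c(-3, -3, -3)),
    NW = rbind(c(5, 5, -3), c(5, 0, -3), c(-3, -3, -3)),
    W  = rbind(c(5, -3, -3), c(5, 0, -3), c(5, -3, -3)),
    SW = rbind(c(-3, -3, -3), c(5, 0, -3), c(5, 5, -3)),
    S  = rbind(c(-3, -3, -3), c(-3, 0, -3), c(5, 5, 5)),
    SE = rbind(c(-3, -3, -3), c(-3, 0, 5), c(-3, 5, 5)))
}

# cross-correlate a 3x3 mask with the interior of gray (exact, no padding)
kirschResponse <- function(gray, mask3) {
  H <- nrow(gray); W <- ncol(gray)
  out <- matrix(0, H - 2L, W - 2L)
  for (di in 0:2) for (dj in 0:2) {
    w <- mask3[di + 1L, dj + 1L]
    if (w != 0)
      out <- out + w * gray[(1L + di):(H - 2L + di), (1L + dj):(W - 2L + dj)]
  }
  out
}

# admissible codes with exactly k of 8 bits set, ascending
ldpAdmissibleCodes <- function(k = 3L) {
  codes <- 0:255
  codes[vapply(codes, function(cc) sum(bitwAnd(cc, bitwShiftL(1L, 0:7)) > 0),
               integer(1)) == k]
}

#' Local directional pattern histogram
#'
#' Per interior pixel, the 8 Kirsch compass responses are taken in absolute
#' value and the `k` strongest set bits of an 8-bit code (ties broken toward
#' the lowest mask index). The `choose(8, k)` admissible codes (56 for the
#' default k = 3), in ascending code order, index the histogram bins.
#'
#' @param gray numeric H x W matrix (any scale), H, W >= 3.
#' @param k number of strongest responses encoded, 1-7 (default 3).
#' @return normalized histogram of length `choose(8, k)`, summing to 1.
#' @export
#' @examples
#' h <- ldpHistogram(matrix(runif(81), 9, 9))
#' sum(h)
ldpHistogram <- function(gray, k = 3L) {
  if (!is.matrix(gray) || nrow(gray) < 3L || ncol(gray) < 3L)
    stopShape("ldpHistogram: image must be at least 3 x 3")
  stopifnot(k >= 1L, k <= 7L)
  masks <- kirschMasks()
  A <- vapply(masks, function(m) abs(as.vector(kirschResponse(gray, m))),
              numeric((nrow(gray) - 2L) * (ncol(gray) - 2L)))
  A <- matrix(A, ncol = 8L)
  m <- nrow(A)
  code <- integer(m)
  for (pass in seq_len(k)) {
    cur <- rep(-Inf, m); idx <- integer(m)
    for (j in 1:8) {
      better <- A[, j] > cur  # strict: ties keep the lower mask index
      cur[better] <- A[better, j]
      idx[better] <- j
    }
    code <- code + bitwShiftL(1L, idx - 1L)
    A[cbind(seq_len(m), idx)] <- -Inf
  }
  admissible <- ldpAdmissibleCodes(k)
  h <- tabulate(match(code, admissible), length(admissible))
  h / sum(h)
}

# 2-D linear convolution via FFT, 'same' output, replicate (nearest-edge)
# padding so DC-free kernels stay DC-free at the boundary
conv2same <- function(im, kern) {
  H <- nrow(im); W <- ncol(im); kh <- nrow(kern); kw <- ncol(kern)
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  ridx <- clampRange(seq_len(H + kh - 1L) - ph, 1L, H)
  cidx <- clampRange(seq_len(W + kw - 1L) - pw, 1L, W)
  P <- im[ridx, cidx, drop = FALSE]
  PH <- nrow(P) + kh - 1L; PW <- ncol(P) + kw - 1L
  A <- matrix(0, PH, PW); A[seq_len(nrow(P)), seq_len(ncol(P))] <- P
  B <- matrix(0, PH, PW); B[1:kh, 1:kw] <- kern
  full <- Re(fft(fft(A) * fft(B), inverse = TRUE)) / (PH * PW)
  full[kh:(kh - 1L + H), kw:(kw - 1L + W), drop = FALSE]
}

# DC-free even Gabor kernel with unit gain at its center frequency
gaborEvenKernel <- function(freq, theta, maxHalf = 24L) {
  sigma <- 0.56 / freq
  h <- min(as.integer(ceiling(2.5 * sigma)), maxHalf)
  xs <- -h:h
  X <- outer(xs, rep(1, length(xs))); Y <- t(X)
  Xr <- X * cos(theta) + Y * sin(theta)
  g <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  kern <- g * cos(2 * pi * freq * Xr)
  kern <- kern - sum(kern) / sum(g) * g  # remove DC
  gain <- sum(kern * cos(2 * pi * freq * Xr))
  kern / gain
}

lfpCenterFreqs <- function(bands) 0.25 / sqrt(2)^(seq_len(bands) - 1L)

#' Local frequency pattern descriptor
#'
#' A band-pass filter bank (radial frequency bands x orientations, DC-free
#' even Gabor kernels with unit gain at their center frequency) is applied to
#' the image; per slot, the rate at which the absolute response exceeds its
#' own 9 x 9 local mean by a margin of 0.35 standard deviations of the
#' input is recorded. Entries lie in \[0, 1\]; a constant image yields all zeros.
#'
#' @param gray numeric H x W matrix scaled to \[0, 1\], H, W >= 8.
#' @param bands number of radial frequency bands (default 5; center
#'   frequencies 0.25 / sqrt(2)^(band-1) cycles/pixel).
#' @param orientations number of orientations (default 6; multiples of
#'   pi/orientations).
#' @return numeric vector of length `bands * orientations`, band-major.
#' @export
lfpHistogram <- function(gray, bands = 5L, orientations = 6L) {
  if (!is.matrix(gray) || nrow(gray) < 8L || ncol(gray) < 8L)
    stopShape("lfpHistogram: image must be at least 8 x 8")
  margin <- 0.35 * sd(as.vector(gray)) + 1e-12
  box <- matrix(1 / 81, 9, 9)
  out <- numeric(bands * orientations)
  freqs <- lfpCenterFreqs(bands)
  slot <- 1L
  for (b in seq_len(bands)) {
    for (o in seq_len(orientations)) {
      kern <- gaborEvenKernel(freqs[b], (o - 1L) * pi / orientations)
      mag <- abs(conv2same(gray, kern))
      localMean <- conv2same(mag, box)
      out[slot] <- mean(mag > localMean + margin)
      slot <- slot + 1L
    }
  }
  out
}

# convex hull area over pixel corners (so a filled axis-aligned square of
# side s has hull area exactly s^2)
hullAreaPixels <- function(rows, cols) {
  pts <- cbind(c(rows - 0.5, rows - 0.5, rows + 0.5, rows + 0.5),
               c(cols - 0.5, cols + 0.5, cols - 0.5, cols + 0.5))
  hull <- chull(pts)
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3L) return(length(rows))
  i2 <- c(2:n, 1L)
  abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
}

#' Connected-component shape descriptors
#'
#' Per component: area (px), perimeter (px), eccentricity, circularity
#' (4 pi A / P^2) and solidity (area over pixel-corner convex-hull area).
#' Each is aggregated over components with mean, sd, min, max, median, IQR,
#' skewness and sum (40 slots), followed by the component count and the
#' foreground fraction (42 slots total). An empty mask yields all zeros.
#'
#' @param mask H x W matrix with values in \{0, 1\}.
#' @return named numeric vector of length 42.
#' @export
#' @examples
#' m <- matrix(0, 32, 32); m[8:24, 8:24] <- 1
#' shapeDescriptors(m)[["shape_solidity_mean"]]
shapeDescriptors <- function(mask) {
  if (!is.matrix(mask) || !all(mask %in% c(0, 1)))
    stop("shapeDescriptors: mask must be a binary matrix")
  statNames <- c("mean", "sd", "min", "max", "median", "iqr", "skew", "sum")
  base <- c("area", "perimeter", "eccentricity", "circularity", "solidity")
  nm <- c(as.vector(t(outer(base, statNames,
                            function(a, b) paste("shape", a, b, sep = "_")))),
          "shape_n_components", "shape_fg_fraction")
  labels <- EBImage::bwlabel(mask)
  nComp <- max(labels)
  if (nComp == 0L) return(setNames(numeric(42L), nm))
  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  shp <- matrix(shp, ncol = ncol(shp), dimnames = dimnames(shp))
  area <- shp[, "s.area"]
  # contour-chain perimeter with the standard 0.95 digitization correction
  contours <- EBImage::ocontour(labels)
  perim <- vapply(contours, function(pts) {
    if (nrow(pts) < 2L) return(4)
    steps <- diff(rbind(pts, pts[1L, , drop = FALSE]))
    max(0.95 * sum(sqrt(rowSums(steps^2))), 4)
  }, numeric(1))
  ecc <- mom[, "m.eccentricity"]
  circ <- 4 * pi * area / perim^2
  solidity <- vapply(seq_len(nComp), function(i) {
    px <- which(labels == i, arr.ind = TRUE)
    area[i] / max(hullAreaPixels(px[, 1], px[, 2]), area[i] * 1e-9)
  }, numeric(1))
  solidity <- pmin(solidity, 1)
  agg <- function(x) c(mean(x), if (length(x) > 1) sd(x) else 0, min(x),
                       max(x), median(x), IQR(x), skewnessPop(x), sum(x))
  vals <- c(vapply(list(area, perim, ecc, circ, solidity), agg, numeric(8L)))
  setNames(c(vals, nComp, mean(mask)), nm)
}

#' RGB/HSV color statistics
#'
#' Mean and sd of each of R, G, B, hue (circular, in turns), saturation and
#' value (12 slots); an 8-bin mass-normalized hue histogram with
#' undefined-hue (zero saturation) pixels assigned to bin 0 (8 slots);
#' grayscale intensity entropy in bits (1 slot); and the Hasler-Suesstrunk
#' colorfulness index (1 slot). 22 slots total.
#'
#' @param tile a [HistologyTile-class] or H x W x 3 array in \[0, 255\].
#' @return named numeric vector of length 22.
#' @export
colorFeatures <- function(tile) {
  px <- if (is(tile, "HistologyTile")) tile@pixels else tile
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stopShape("colorFeatures: input must have exactly 3 channels")
  r <- as.vector(px[, , 1]); g <- as.vector(px[, , 2]); b <- as.vector(px[, , 3])
  hsv <- rgb2hsv(rbind(r, g, b), maxColorValue = 255)
  h <- hsv[1, ]; s <- hsv[2, ]; v <- hsv[3, ]
  ang <- 2 * pi * h
  Cbar <- mean(cos(ang)); Sbar <- mean(sin(ang))
  hMean <- (atan2(Sbar, Cbar) / (2 * pi)) %% 1
  Rbar <- sqrt(Cbar^2 + Sbar^2)
  hSd <- sqrt(max(0, -2 * log(max(Rbar, 1e-12)))) / (2 * pi)
  sdp <- function(x) if (length(x) > 1) sd(x) else 0
  sc <- function(x) x / 255
  stats12 <- c(mean(sc(r)), sdp(sc(r)), mean(sc(g)), sdp(sc(g)),
               mean(sc(b)), sdp(sc(b)), hMean, hSd,
               mean(s), sdp(s), mean(v), sdp(v))
  bins <- pmin(floor(h * 8), 7)
  bins[s == 0] <- 0  # undefined hue convention
  hueHist <- tabulate(bins + 1L, 8L) / length(h)
  lum <- 0.299 * r + 0.587 * g + 0.114 * b
  ent <- entropyBits(tabulate(pmin(floor(lum), 255) + 1L, 256L))
  rg <- sc(r) - sc(g); yb <- 0.5 * (sc(r) + sc(g)) - sc(b)
  colorfulness <- sqrt(sdp(rg)^2 + sdp(yb)^2) +
    0.3 * sqrt(mean(rg)^2 + mean(yb)^2)
  setNames(c(stats12, hueHist, ent, colorfulness),
           c("color_r_mean", "color_r_sd", "color_g_mean", "color_g_sd",
             "color_b_mean", "color_b_sd", "color_h_mean", "color_h_sd",
             "color_s_mean", "color_s_sd", "color_v_mean", "color_v_sd",
             paste0("color_hue_bin", 0:7), "color_entropy",
             "color_colorfulness"))
}

#' The default 150-slot feature registry
#'
#' 56 LDP + 30 LFP texture slots (86), 42 shape slots and 22 color slots,
#' in extraction order. Category shares (57.3\%, 28\%, 14.7\%) fall inside
#' the reported 50-60\% / 25-30\% / 10-15\% bands.
#'
#' @param version registry version string.
#' @return a [FeatureRegistry-class].
#' @export
#' @examples
#' table(defaultRegistry()@categories)
defaultRegistry <- function(version = "1.0") {
  ldpNames <- sprintf("ldp_c%03d", ldpAdmissibleCodes(3L))
  lfpNames <- as.vector(t(outer(1:5, 1:6,
                                function(b, o) sprintf("lfp_b%d_o%d", b, o))))
  statNames <- c("mean", "sd", "min", "max", "median", "iqr", "skew", "sum")
  base <- c("area", "perimeter", "eccentricity", "circularity", "solidity")
  shapeNames <- c(as.vector(t(outer(base, statNames,
                    function(a, b) paste("shape", a, b, sep = "_")))),
                  "shape_n_components", "shape_fg_fraction")
  colorNames <- c("color_r_mean", "color_r_sd", "color_g_mean", "color_g_sd",
                  "color_b_mean", "color_b_sd", "color_h_mean", "color_h_sd",
                  "color_s_mean", "color_s_sd", "color_v_mean", "color_v_sd",
                  paste0("color_hue_bin", 0:7), "color_entropy",
                  "color_colorfulness")
  new("FeatureRegistry",
      slotNames = c(ldpNames, lfpNames, shapeNames, colorNames),
      categories = c(rep("texture", length(ldpNames) + length(lfpNames)),
                     rep("shape", length(shapeNames)),
                     rep("color", length(colorNames))),
      version = version)
}

# Otsu foreground on the hematoxylin concentration channel
otsuForeground <- function(tile) {
  odm <- matrix(rgbToOD(tile), ncol = 3L)
  Ch <- odConcentrations(odm, defaultStainMatrix())[, 1]
  Ch <- matrix(Ch, nrow = dim(tile@pixels)[1])
  rng <- range(Ch)
  if (diff(rng) < 1e-9) return(matrix(0, nrow(Ch), ncol(Ch)))
  Cn <- (Ch - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(Cn), range = c(0, 1))
  (Cn > th) + 0
}

#' Extract the full 150-slot feature vector for a tile
#'
#' Concatenates the LDP (56), LFP (30), shape (42) and color (22)
#' descriptors in registry order. Shape features use the tile's mask when
#' present, otherwise an Otsu foreground estimate on the hematoxylin
#' concentration channel (logged via `message`).
#'
#' @param tile a preprocessed [HistologyTile-class].
#' @param registry a [FeatureRegistry-class] (default [defaultRegistry()]).
#' @param label optional 0/1 label attached to the result.
#' @return a [FeatureVector-class].
#' @export
extractFeatures <- function(tile, registry = defaultRegistry(), label = NA) {
  stopifnot(is(tile, "HistologyTile"), is(registry, "FeatureRegistry"))
  px <- tile@pixels
  gray <- (0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]) / 255
  mask <- tile@mask
  if (is.null(mask)) {
    message("extractFeatures: no mask for tile '", tile@id,
            "'; using Otsu foreground estimate")
    mask <- otsuForeground(tile)
  }
  vals <- c(ldpHistogram(gray * 255), lfpHistogram(gray),
            shapeDescriptors(mask), colorFeatures(tile))
  if (length(vals) != length(registry@slotNames))
    stop("extractFeatures: registry mismatch - extracted ", length(vals),
         " values for ", length(registry@slotNames), " registry slots")
  new("FeatureVector", values = setNames(as.numeric(vals),
                                         registry@slotNames),
      registry = registry, label = as.integer(label))
}

#' Extract a feature table for a list of tiles
#'
#' @param tiles list of [HistologyTile-class] objects.
#' @param registry a [FeatureRegistry-class].
#' @param labels optional 0/1 labels aligned with `tiles`.
#' @return data.frame with columns `id`, `label`, then one column per
#'   registry slot.
#' @export
extractFeatureTable <- function(tiles, registry = defaultRegistry(),
                                labels = NULL) {
  rows <- lapply(seq_along(tiles), function(i) {
    fv <- extractFeatures(tiles[[i]], registry,
                          label = if (is.null(labels)) NA else labels[i])
    c(list(id = tiles[[i]]@id,
           label = if (is.null(labels)) NA_integer_ else as.integer(labels[i])),
      as.list(fv@values))
  })
  do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
}

#' Feature table and registry input/output
#'
#' CSV feature tables have columns `id`, `label`, then the registry-named
#' slots; the registry descriptor round-trips through JSON.
#'
#' @param x a feature-table data.frame or [FeatureRegistry-class].
#' @param path file path.
#' @return readers return the parsed object; writers the path, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname writeFeatureTable
#' @export
writeRegistryJSON <- function(x, path) {
  stopifnot(is(x, "FeatureRegistry"))
  jsonlite::write_json(list(version = x@version, slots = data.frame(
    name = x@slotNames, category = x@categories)), path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readRegistryJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("FeatureRegistry", slotNames = obj$slots$name,
      categories = obj$slots$category, version = obj$version)
}
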