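# The 150-slot feature bank: LDP, LFP, shape and color descriptors.

test_that("LDP histogram matches the per-patch brute-force oracle exactly", {
  set.seed(11)
  for (r in 1:50) {
    g <- matrix(sample(0:255, 81, replace = TRUE), 9, 9)
    expect_equal(ldpHistogram(g), bruteForceLDP(g), tolerance = 0)
  }
})

test_that("LDP histogram normalizes, tie-breaks and validates input", {
  h <- ldpHistogram(matrix(runif(30 * 30), 30, 30))
  expect_equal(sum(h), 1, tolerance = 1e-12)
  expect_length(h, 56L)
  # constant image: all responses tie, lowest mask indices win -> one bin
  hc <- ldpHistogram(matrix(42, 12, 12))
  expect_equal(max(hc), 1)
  expect_equal(which(hc == 1),
               match(7L, mitoscope:::ldpAdmissibleCodes(3L)))
  expect_error(ldpHistogram(matrix(1, 2, 5)), "3 x 3")
})

test_that("LFP responds to matched sinusoids and is silent on constants", {
  expect_true(all(lfpHistogram(matrix(0.7, 24, 24)) == 0))
  freqs <- mitoscope:::lfpCenterFreqs(5)
  xs <- 1:64
  for (b in c(1L, 3L, 5L)) {
    img <- outer(rep(1, 64), 0.5 + 0.4 * sin(2 * pi * freqs[b] * xs))
    v <- lfpHistogram(img)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(which.max(v), (b - 1L) * 6L + 4L)
  }
  # wave along rows matches orientation 1
  img <- outer(0.5 + 0.4 * sin(2 * pi * freqs[2] * xs), rep(1, 64))
  expect_equal(which.max(lfpHistogram(img)), 7L)
  expect_error(lfpHistogram(matrix(1, 4, 4)), "8 x 8")
})

test_that("shape descriptors match analytic geometry", {
  disk <- diskMask(64, 20)
  v <- shapeDescriptors(disk)
  expect_gte(v[["shape_circularity_mean"]], 0.85)
  expect_lte(v[["shape_circularity_mean"]], 1.05)
  expect_gte(v[["shape_solidity_mean"]], 0.95)
  expect_lte(v[["shape_eccentricity_mean"]], 0.2)
  sq <- matrix(0, 32, 32); sq[8:24, 8:24] <- 1
  expect_equal(shapeDescriptors(sq)[["shape_solidity_mean"]], 1.0)
  ell <- ellipseMask(120, 40, 20)
  expect_equal(shapeDescriptors(ell)[["shape_eccentricity_mean"]],
               sqrt(1 - (20 / 40)^2), tolerance = 0.05)
  expect_equal(shapeDescriptors(matrix(0, 16, 16)),
               setNames(numeric(42), names(v)))
  expect_error(shapeDescriptors(matrix(0.5, 8, 8)), "binary")
})

test_that("shape areas and counts agree with a pixel-counting oracle", {
  set.seed(21)
  for (r in 1:50) {
    m <- matrix(0, 24, 24)
    for (b in seq_len(sample(1:4, 1))) {
      i <- sample(3:18, 1); j <- sample(3:18, 1)
      h <- sample(2:5, 1); w <- sample(2:5, 1)
      m[i:(i + h), j:(j + w)] <- 1
    }
    oracle <- bruteForceComponents(m)
    v <- shapeDescriptors(m)
    expect_equal(v[["shape_n_components"]], length(oracle))
    expect_equal(v[["shape_area_sum"]], sum(oracle))
    expect_equal(v[["shape_area_max"]], max(oracle))
  }
})

test_that("color features handle degenerate and bichromatic inputs", {
  gray <- array(rep(seq(30, 220, length.out = 64), 3), c(8, 8, 3))
  vg <- colorFeatures(gray)
  expect_equal(vg[["color_s_mean"]], 0)
  expect_equal(vg[["color_s_sd"]], 0)
  expect_equal(vg[["color_hue_bin0"]], 1)
  const <- colorFeatures(array(128, c(8, 8, 3)))
  expect_true(all(const[c("color_r_sd", "color_g_sd", "color_b_sd",
                          "color_entropy")] == 0))
  half <- array(0, c(10, 10, 3))
  half[1:5, , 1] <- 255; half[6:10, , 3] <- 255
  vh <- colorFeatures(half)
  expect_equal(vh[["color_hue_bin0"]], 0.5)  # red
  expect_equal(vh[["color_hue_bin5"]], 0.5)  # blue
})

test_that("the assembled vector has 150 slots in the reported proportions", {
  reg <- defaultRegistry()
  expect_length(reg@slotNames, 150L)
  counts <- table(reg@categories)
  expect_equal(as.integer(counts[c("texture", "shape", "color")]),
               c(86L, 42L, 22L))
  shares <- counts / 150
  expect_true(shares[["texture"]] >= 0.5 && shares[["texture"]] <= 0.6)
  expect_true(shares[["shape"]] >= 0.25 && shares[["shape"]] <= 0.30)
  expect_true(shares[["color"]] >= 0.10 && shares[["color"]] <= 0.15)
  tile <- genHETile(tileGenParams(side = 64, nNuclei = 8, nMitotic = 2,
                                  seed = 4))
  fv <- extractFeatures(tile, reg)
  expect_length(fv@values, 150L)
  expect_true(all(is.finite(fv@values)))
  # determinism on identical tiles
  fv2 <- extractFeatures(genHETile(tileGenParams(side = 64, nNuclei = 8,
                                                 nMitotic = 2, seed = 4)),
                         reg)
  expect_identical(fv@values, fv2@values)
  # maskless tiles fall back to the Otsu foreground, with a log message
  noMask <- histologyTile(tilePixels(tile), id = "nm")
  expect_message(extractFeatures(noMask, reg), "Otsu")
  # registry mismatch errors
  small <- new("FeatureRegistry", slotNames = c("a", "b"),
               categories = c("texture", "shape"), version = "x")
  expect_error(extractFeatures(tile, small), "registry mismatch")
})

test_that("feature tables and registries round-trip through CSV/JSON", {
  reg <- defaultRegistry()
  tiles <- smokeTiles(2, seedBase = 40, side = 64, nNuclei = 6,
                      nMitotic = 1)
  tab <- extractFeatureTable(tiles, reg, labels = c(1L, 0L))
  expect_equal(dim(tab), c(2L, 152L))
  csv <- tempfile(fileext = ".csv")
  writeFeatureTable(tab, csv)
  back <- readFeatureTable(csv)
  expect_equal(back$label, c(1L, 0L))
  expect_equal(as.numeric(back[1, -(1:2)]), as.numeric(tab[1, -(1:2)]),
               tolerance = 1e-12)
  js <- tempfile(fileext = ".json")
  writeRegistryJSON(reg, js)
  reg2 <- readRegistryJSON(js)
  expect_identical(reg2@slotNames, reg@slotNames)
  expect_identical(reg2@categories, reg@categories)
})
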