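# Optical-density stain model, reference normalization, preprocessing and
# dataset splitting.

test_that("OD transform round-trips the full 8-bit range within one level", {
  x <- array(rep(0:255, length.out = 16 * 16 * 3), c(16, 16, 3))
  od <- rgbToOD(x)
  expect_true(all(od[x <= 255] >= 0))
  back <- odToRGB(od)
  expect_lte(max(abs(back - x)), 1)
  # white maps to (near) zero OD
  white <- rgbToOD(array(255, c(2, 2, 3)))
  expect_lt(max(abs(white)), 2e-5)
  # darker pixel of the same hue has elementwise larger OD
  darker <- rgbToOD(array(60, c(1, 1, 3)))
  lighter <- rgbToOD(array(200, c(1, 1, 3)))
  expect_true(all(darker >= lighter))
  expect_error(rgbToOD(array(1, c(4, 4, 2))), "3 channels")
})

test_that("stain profiles are recovered from rendered tiles", {
  tile <- genHETile(tileGenParams(side = 96, nNuclei = 14, nMitotic = 3,
                                  stainPerturbation = 0.08, seed = 2))
  prof <- estimateStainProfile(tile)
  expect_equal(sqrt(rowSums(prof@stainMatrix^2)), c(1, 1), tolerance = 1e-9)
  expect_true(all(prof@stainMatrix >= 0))
  truth <- attr(tile, "stainMatrix")
  angles <- acos(pmin(1, rowSums(prof@stainMatrix * truth))) * 180 / pi
  expect_lt(max(angles), 10)
})

test_that("degenerate references are rejected or fall back per config", {
  blank <- histologyTile(array(250, c(32, 32, 3)))
  expect_error(estimateStainProfile(blank), "degenerate")
  grayRamp <- array(rep(seq(40, 200, length.out = 32), 32 * 3), c(32, 32, 3))
  gray <- histologyTile(grayRamp)
  expect_error(estimateStainProfile(gray), "chroma")
  prof <- estimateStainProfile(gray, fallbackDefault = TRUE)
  expect_equal(prof@stainMatrix, mitoscope:::defaultStainMatrix(),
               tolerance = 1e-9)
})

test_that("normalization is a near-identity on the reference and idempotent", {
  tile <- genHETile(tileGenParams(side = 96, nNuclei = 14, nMitotic = 3,
                                  seed = 5))
  prof <- estimateStainProfile(tile)
  once <- normalizeToReference(tile, prof)
  expect_lte(mean(abs(tilePixels(once) - tilePixels(tile))), 3)
  twice <- normalizeToReference(once, prof)
  expect_lte(mean(abs(tilePixels(twice) - tilePixels(once))),
             mean(abs(tilePixels(once) - tilePixels(tile))) + 1)
  # all-background tile passes through nearly unchanged
  bg <- histologyTile(array(254, c(32, 32, 3)) -
                        array(runif(32 * 32 * 3, 0, 1), c(32, 32, 3)))
  suppressMessages(bgn <- normalizeToReference(bg, prof))
  expect_lte(mean(abs(tilePixels(bgn) - tilePixels(bg))), 3)
})

test_that("normalization pulls stain-perturbed pairs together", {
  ref <- genHETile(tileGenParams(side = 96, nNuclei = 14, nMitotic = 3,
                                 seed = 99))
  prof <- estimateStainProfile(ref)
  improved <- 0L
  for (s in 1:6) {
    a <- genHETile(tileGenParams(side = 96, nNuclei = 14, nMitotic = 3,
                                 stainPerturbation = 0.12, seed = s,
                                 stainSeed = 1000 + s))
    b <- genHETile(tileGenParams(side = 96, nNuclei = 14, nMitotic = 3,
                                 stainPerturbation = 0.12, seed = s,
                                 stainSeed = 2000 + s))
    pre <- mean(abs(tilePixels(a) - tilePixels(b)))
    post <- mean(abs(tilePixels(normalizeToReference(a, prof)) -
                       tilePixels(normalizeToReference(b, prof))))
    if (post < pre) improved <- improved + 1L
  }
  expect_gte(improved, 5L)
})

test_that("preprocess resizes, median-filters and keeps masks binary", {
  tile <- genHETile(tileGenParams(side = 48, nNuclei = 6, nMitotic = 1,
                                  seed = 3))
  out <- preprocessTile(tile, side = 227L)
  expect_equal(dim(tilePixels(out)), c(227L, 227L, 3L))
  expect_true(all(tileMask(out) %in% c(0, 1)))
  expect_error(preprocessTile(tile, side = 64, medianKernel = 4), "odd")
  # constant image unchanged by the median filter
  const <- histologyTile(array(120, c(64, 64, 3)))
  expect_equal(tilePixels(preprocessTile(const, side = 64)),
               tilePixels(const))
  # salt-and-pepper noise: >= 90% of impulse pixels removed by 3x3 median
  set.seed(7)
  base <- array(120, c(64, 64, 3))
  hits <- sample(64 * 64, round(0.01 * 64 * 64))
  for (ch in 1:3) base[cbind(arrayInd(hits, c(64, 64)), ch)] <-
    rep(c(0, 255), length.out = length(hits))
  noisy <- histologyTile(base)
  clean <- preprocessTile(noisy, side = 64)
  impulsesBefore <- sum(abs(base - 120) > 60)
  impulsesAfter <- sum(abs(tilePixels(clean) - 120) > 60)
  expect_lte(impulsesAfter, 0.1 * impulsesBefore)
})

test_that("dataset splits are exact, disjoint, exhaustive, reproducible", {
  sp <- splitSpec(seed = 7)
  parts <- splitDataset(1:100, rep(0:1, 50), sp)
  expect_equal(lengths(parts), c(train = 70L, val = 15L, test = 15L))
  expect_identical(parts, splitDataset(1:100, rep(0:1, 50), sp))
  for (n in c(10L, 57L, 341L, 1000L)) {
    labels <- rep_len(c(0, 0, 0, 1, 1), n)
    p <- splitDataset(seq_len(n), labels, splitSpec(seed = n))
    expect_equal(sort(unlist(p, use.names = FALSE)), seq_len(n))
    expect_equal(sum(lengths(p)), n)
  }
  # stratified 60/40 at 50/25/25 stays within one item of proportionality
  labels <- rep(c(0, 1), c(60, 40))
  p <- splitDataset(seq_len(100), labels,
                    splitSpec(c(0.5, 0.25, 0.25), seed = 1))
  for (part in p) {
    n1 <- sum(labels[part])
    expect_lte(abs(n1 - 0.4 * length(part)), 1)
  }
  expect_error(splitDataset(1:4, c(0, 0, 0, 1), splitSpec(seed = 1)),
               "stratification")
})
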