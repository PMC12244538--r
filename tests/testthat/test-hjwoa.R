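# Wrapper feature selection: subset fitness, the hybrid loop, reporting.

test_that("subset fitness honors the F1 identities and degenerate cases", {
  # harmonic-mean identities checked on the F1 kernel itself
  f1 <- mitoscope:::f1FromPredictions
  truth <- c(rep(1L, 500), rep(0L, 500))
  # precision = recall = p  =>  F1 = p
  pred <- truth
  pred[1:100] <- 0L; pred[501:600] <- 1L  # 100 FN and 100 FP: P = R = 0.8
  expect_equal(f1(pred, truth), 0.8, tolerance = 1e-12)
  # precision 1, recall 0.988 => F1 = 2 * 0.988 / 1.988
  truth2 <- c(rep(1L, 1000), rep(0L, 200))
  pred2 <- truth2; pred2[1:12] <- 0L
  expect_equal(f1(pred2, truth2), 2 * 0.988 / 1.988, tolerance = 1e-12)

  tab <- genFeatureTable(tableGenParams(nSamples = 60, d = 6,
                                        nInformative = 2, effectSize = 2,
                                        seed = 1))
  cfg <- hjwoaConfig(seed = 1)
  expect_equal(subsetFitness(rep(0L, 6), tab$X, tab$y, cfg), 0)
  expect_error(subsetFitness(rep(1L, 6), tab$X, rep(1L, 60), cfg),
               "both classes")
})

test_that("the fitness cache skips repeat classifier work", {
  tab <- genFeatureTable(tableGenParams(nSamples = 60, d = 8,
                                        nInformative = 2, effectSize = 2,
                                        seed = 2))
  cfg <- hjwoaConfig(seed = 2)
  cache <- new.env(); cache$memo <- new.env(); cache$calls <- 0L
  mask <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  a <- subsetFitness(mask, tab$X, tab$y, cfg, cache = cache)
  b <- subsetFitness(mask, tab$X, tab$y, cfg, cache = cache)
  expect_identical(a, b)
  expect_identical(cache$calls, 1L)
})

test_that("selection runs are deterministic given the seed", {
  tab <- genFeatureTable(tableGenParams(nSamples = 80, d = 15,
                                        nInformative = 3, effectSize = 2,
                                        seed = 3))
  cfg <- hjwoaConfig(population = 10, iterations = 8, seed = 5)
  a <- hjwoaRun(tab$X, tab$y, config = cfg)
  b <- hjwoaRun(tab$X, tab$y, config = cfg)
  expect_identical(a@mask, b@mask)
  expect_identical(a@fitness, b@fitness)
  expect_identical(a@history, b@history)
  expect_true(all(diff(a@history) >= 0))
  expect_equal(a@nSelected, sum(a@mask))
})

test_that("the hybrid tracks the exhaustive oracle as dimension grows", {
  for (d in c(8L, 10L)) {
    tab <- genFeatureTable(tableGenParams(nSamples = 120, d = d,
                                          nInformative = 3, effectSize = 2,
                                          seed = d))
    ocfg <- hjwoaConfig(seed = d)
    oracle <- exhaustiveSelection(tab$X, tab$y, ocfg)
    # same config seed: the search optimizes exactly the objective the
    # oracle enumerated (same cross-validation folds)
    run <- hjwoaRun(tab$X, tab$y,
                    config = hjwoaConfig(population = 24, iterations = 40,
                                         seed = d))
    found <- subsetFitness(run@mask, tab$X, tab$y, ocfg)
    expect_lte(oracle$fitness - found, 0.02)
  }
})

test_that("pure-noise columns leave the oracle optimum essentially flat", {
  base <- genFeatureTable(tableGenParams(nSamples = 120, d = 6,
                                         nInformative = 3, effectSize = 2,
                                         seed = 9))
  cfg <- hjwoaConfig(seed = 9)
  o1 <- exhaustiveSelection(base$X, base$y, cfg)
  Xn <- cbind(base$X, matrix(rnorm(120 * 3), 120, 3))
  colnames(Xn) <- sprintf("f%03d", 1:9)
  o2 <- exhaustiveSelection(Xn, base$y, cfg)
  # enlarging the candidate set cannot lose the old optimum; noise may only
  # add spurious slack within CV resolution
  expect_gte(o2$fitness, o1$fitness - 1e-12)
  expect_lte(o2$fitness, o1$fitness + 0.02)
})

test_that("informative features are recovered on a desk-scale problem", {
  tab <- genFeatureTable(tableGenParams(nSamples = 150, d = 30,
                                        nInformative = 4, effectSize = 2,
                                        seed = 13))
  run <- hjwoaRun(tab$X, tab$y,
                  config = hjwoaConfig(population = 20, iterations = 25,
                                       seed = 14))
  expect_gte(sum(tab$informative %in% which(run@mask == 1L)), 3L)
})

test_that("selection reports expose counts, shares and flags", {
  reg <- defaultRegistry()
  mask <- integer(150)
  mask[which(reg@categories == "texture")[1:10]] <- 1L
  res <- new("SelectionResult", mask = mask, fitness = 0.9,
             history = c(0.8, 0.9),
             categoryShares = mitoscope:::categoryShares(mask, reg),
             nSelected = 10L, seed = 1L, config = list())
  rep <- selectionReport(res, reg)
  expect_equal(rep$categoryShares$texture, 1.0)
  expect_equal(rep$categoryShares$shape, 0.0)
  expect_false(rep$flags$nSelectedInReportedRange)
  expect_equal(sum(unlist(rep$categoryShares)), 1)
  # empty selection flags
  res0 <- new("SelectionResult", mask = integer(150), fitness = 0,
              history = numeric(0),
              categoryShares = mitoscope:::categoryShares(integer(150), reg),
              nSelected = 0L, seed = 1L, config = list())
  rep0 <- selectionReport(res0, reg)
  expect_true(rep0$flags$emptySelection)
  expect_equal(sum(unlist(rep0$categoryShares)), 0)
  js <- tempfile(fileext = ".json")
  writeSelectionJSON(res, reg, js)
  expect_equal(jsonlite::read_json(js)$nSelected, 10L)
})
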