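# Confusion counts and the eleven-metric suite.

test_that("confusion tallies from labels are exact and conserved", {
  cc <- confusionFromLabels(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(c(cc@tp, cc@tn, cc@fp, cc@fn), c(2L, 2L, 0L, 0L))
  comp <- confusionFromLabels(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(c(comp@tp, comp@tn), c(0L, 0L))
  set.seed(1)
  p <- rbinom(1000, 1, 0.4); t <- rbinom(1000, 1, 0.5)
  cc2 <- confusionFromLabels(p, t)
  expect_equal(cc2@tp + cc2@fp + cc2@tn + cc2@fn, 1000L)
  expect_error(confusionFromLabels(c(1, 0), c(1, 0, 1)), "lengths")
  expect_error(confusionFromLabels(c(2, 0), c(1, 0)), "binary")
})

test_that("the worked example and the perfect classifier come out right", {
  r <- metricSuite(confusionCounts(tp = 9, fp = 1, tn = 9, fn = 1))
  expect_equal(r@sen, 0.9); expect_equal(r@spec, 0.9)
  expect_equal(r@ba, 0.9)
  expect_equal(r@csi, 9 / 11, tolerance = 1e-12)
  expect_equal(r@fmi, 0.9, tolerance = 1e-12)
  p <- metricSuite(confusionCounts(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(c(p@sen, p@spec, p@acc, p@fMeasure, p@csi, p@ba, p@fmi,
                 p@mk), rep(1, 8))
  expect_equal(c(p@fpr, p@fnr, p@nlr), rep(0, 3))
})

test_that("identities hold to 1e-12 over random confusion tables", {
  set.seed(3)
  for (i in 1:1000) {
    counts <- sample(0:200, 4, replace = TRUE)
    if (sum(counts) == 0) counts[1] <- 1
    r <- metricSuite(confusionCounts(counts[1], counts[2], counts[3],
                                     counts[4]))
    deg <- r@degenerate
    if (!any(c("sen", "spec") %in% deg)) {
      expect_equal(r@ba, (r@sen + r@spec) / 2, tolerance = 1e-12)
      expect_equal(r@fpr, 1 - r@spec, tolerance = 1e-12)
      expect_equal(r@fnr, 1 - r@sen, tolerance = 1e-12)
      if (r@spec > 0)
        expect_equal(r@nlr, (1 - r@sen) / r@spec, tolerance = 1e-12)
    }
    if (!any(c("sen", "precision") %in% deg))
      expect_equal(r@fmi, sqrt(r@precision * r@sen), tolerance = 1e-12)
    if (counts[1] > 0)
      expect_lte(r@csi, min(r@sen, r@precision) + 1e-12)
  }
})

test_that("metric computation is invariant to sample order", {
  set.seed(7)
  p <- rbinom(400, 1, 0.3); t <- rbinom(400, 1, 0.4)
  perm <- sample(400)
  a <- reportValues(metricSuite(confusionFromLabels(p, t)))
  b <- reportValues(metricSuite(confusionFromLabels(p[perm], t[perm])))
  expect_identical(a, b)
})

test_that("zero denominators yield the sentinel plus a flag", {
  r <- metricSuite(confusionCounts(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(all(c("sen", "precision") %in% r@degenerate))
  expect_equal(r@sen, 0)
  expect_equal(r@spec, 1)
  expect_error(metricSuite(confusionCounts(0, 0, 0, 0)))
  # flagged reports still serialize
  js <- tempfile(fileext = ".json")
  writeMetricReportJSON(r, js)
  parsed <- jsonlite::read_json(js)
  expect_true("sen" %in% unlist(parsed$degenerate))
})

test_that("comparison CSVs follow the standard column order", {
  reps <- list(a = metricSuite(confusionCounts(9, 1, 9, 1)),
               b = metricSuite(confusionCounts(8, 2, 8, 2)))
  csv <- tempfile(fileext = ".csv")
  writeMetricComparisonCSV(reps, csv)
  tab <- read.csv(csv, check.names = FALSE)
  expect_equal(colnames(tab),
               c("Method", "Sen", "Spec", "Acc", "F-measure", "CSI", "BA",
                 "FM", "MK", "NLR", "FPR", "FNR"))
  expect_equal(tab$BA[1], 0.9)
})

test_that("detections are scored by the centroid-within-mask rule", {
  truth <- matrix(0, 40, 40)
  truth[5:12, 5:12] <- 1
  truth[25:32, 25:32] <- 1
  hit <- data.frame(row = 7.5, col = 7.5, area = 60, score = 0.9)
  miss <- data.frame(row = 18, col = 18, area = 20, score = 0.6)
  sc <- scoreDetections(rbind(hit, miss), truth)
  expect_equal(c(sc$tp, sc$fp, sc$fn), c(1L, 1L, 1L))
  expect_equal(sc$f1, 2 * 1 / (2 * 1 + 1 + 1))
  # duplicate detections on one object count once
  sc2 <- scoreDetections(rbind(hit, hit), truth)
  expect_equal(c(sc2$tp, sc2$fp, sc2$fn), c(1L, 1L, 1L))
  empty <- scoreDetections(postprocessDetections(matrix(0, 40, 40)), truth)
  expect_equal(empty$tp, 0L)
  expect_equal(empty$fn, 2L)
})
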