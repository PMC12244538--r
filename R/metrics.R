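# Confusion-count computation and the eleven-metric evaluation suite:
# sensitivity, specificity, accuracy, F-measure, critical success index,
# balanced accuracy, Fowlkes-Mallows index, markedness, negative likelihood
# ratio, and the false positive/negative rates (plus precision and NPV,
# which several of them are built from).

#' Build confusion counts
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return a [ConfusionCounts-class].
#' @export
#' @examples
#' confusionCounts(tp = 9, fp = 1, tn = 9, fn = 1)
confusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionCounts", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn))
}

#' Tally a 2 x 2 confusion table from binary labels
#'
#' @param predicted,truth equal-length 0/1 vectors.
#' @return a [ConfusionCounts-class].
#' @export
confusionFromLabels <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stopShape("confusionFromLabels: predicted and truth lengths differ")
  predicted <- as.integer(predicted); truth <- as.integer(truth)
  if (!all(predicted %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L)))
    stop("confusionFromLabels: values must be binary")
  confusionCounts(tp = sum(predicted == 1L & truth == 1L),
                  fp = sum(predicted == 1L & truth == 0L),
                  tn = sum(predicted == 0L & truth == 0L),
                  fn = sum(predicted == 0L & truth == 1L))
}

#' Compute the eleven-metric suite from confusion counts
#'
#' sen = TP/(TP+FN); spec = TN/(TN+FP); acc = (TP+TN)/n;
#' precision = TP/(TP+FP); F = 2 P sen/(P + sen); csi = TP/(TP+FN+FP);
#' ba = (sen+spec)/2; fmi = sqrt(precision * sen);
#' npv = TN/(TN+FN); mk = precision + npv - 1; nlr = (1-sen)/spec;
#' fpr = 1 - spec; fnr = 1 - sen. Metrics whose denominator is zero are
#' reported as the sentinel 0 and named in the report's `degenerate` slot,
#' so reports are always serializable.
#'
#' @param counts a [ConfusionCounts-class].
#' @return a [MetricReport-class].
#' @export
#' @examples
#' metricSuite(confusionCounts(tp = 9, fp = 1, tn = 9, fn = 1))
metricSuite <- function(counts) {
  stopifnot(is(counts, "ConfusionCounts"))
  validObject(counts)
  tp <- counts@tp; fp <- counts@fp; tn <- counts@tn; fn <- counts@fn
  deg <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) { deg <<- c(deg, name); 0 } else num / den
  }
  sen <- rate(tp, tp + fn, "sen")
  spc <- rate(tn, tn + fp, "spec")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  precision <- rate(tp, tp + fp, "precision")
  fMeasure <- rate(2 * precision * sen, precision + sen, "fMeasure")
  csi <- rate(tp, tp + fn + fp, "csi")
  npv <- rate(tn, tn + fn, "npv")
  ba <- if (any(c("sen", "spec") %in% deg)) { deg <- c(deg, "ba"); 0 } else
    (sen + spc) / 2
  fmi <- if (any(c("sen", "precision") %in% deg)) { deg <- c(deg, "fmi"); 0 } else
    sqrt(precision * sen)
  mk <- if (any(c("precision", "npv") %in% deg)) { deg <- c(deg, "mk"); 0 } else
    precision + npv - 1
  nlr <- if (spc == 0 || "sen" %in% deg) { deg <- c(deg, "nlr"); 0 } else
    (1 - sen) / spc
  fpr <- if ("spec" %in% deg) { deg <- c(deg, "fpr"); 0 } else 1 - spc
  fnr <- if ("sen" %in% deg) { deg <- c(deg, "fnr"); 0 } else 1 - sen
  new("MetricReport", sen = sen, spec = spc, acc = acc,
      precision = precision, fMeasure = fMeasure, csi = csi, ba = ba,
      fmi = fmi, mk = mk, nlr = nlr, fpr = fpr, fnr = fnr, npv = npv,
      degenerate = unique(deg))
}

#' Extract metric values as a named vector
#'
#' @param report a [MetricReport-class].
#' @return named numeric vector in the standard column order.
#' @export
reportValues <- function(report) {
  stopifnot(is(report, "MetricReport"))
  c(sen = report@sen, spec = report@spec, acc = report@acc,
    fMeasure = report@fMeasure, csi = report@csi, ba = report@ba,
    fmi = report@fmi, mk = report@mk, nlr = report@nlr, fpr = report@fpr,
    fnr = report@fnr, precision = report@precision, npv = report@npv)
}

#' Write a metric report to JSON
#'
#' @param report a [MetricReport-class].
#' @param path output path.
#' @param extra optional named list merged into the JSON object.
#' @return the path, invisibly.
#' @export
writeMetricReportJSON <- function(report, path, extra = list()) {
  v <- reportValues(report)
  obj <- c(as.list(v), list(degenerate = report@degenerate), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a multi-run metric comparison as CSV
#'
#' Columns follow the standard comparison order: Sen, Spec, Acc, F-measure,
#' CSI, BA, FM, MK, NLR, FPR, FNR.
#'
#' @param reports named list of [MetricReport-class] objects (one per
#'   method/run).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMetricComparisonCSV <- function(reports, path) {
  cols <- c("sen", "spec", "acc", "fMeasure", "csi", "ba", "fmi", "mk",
            "nlr", "fpr", "fnr")
  tab <- t(vapply(reports, function(r) reportValues(r)[cols],
                  numeric(length(cols))))
  colnames(tab) <- c("Sen", "Spec", "Acc", "F-measure", "CSI", "BA", "FM",
                     "MK", "NLR", "FPR", "FNR")
  df <- data.frame(Method = names(reports), tab, check.names = FALSE,
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Object-level detection scoring by the centroid-within-mask rule
#'
#' A detection counts as a true positive when its centroid falls inside an
#' unmatched ground-truth component; remaining detections are false
#' positives and unmatched truth components false negatives.
#'
#' @param detections data.frame from [postprocessDetections()] (columns
#'   `row`, `col`).
#' @param truthMask H x W 0/1 matrix of true mitotic figures.
#' @return list with `tp`, `fp`, `fn` and `f1`.
#' @export
scoreDetections <- function(detections, truthMask) {
  labels <- EBImage::bwlabel(truthMask)
  nTruth <- max(labels)
  matched <- logical(nTruth)
  tp <- 0L; fp <- 0L
  if (nrow(detections)) {
    for (i in seq_len(nrow(detections))) {
      r <- as.integer(round(detections$row[i])) + 1L  # 0-based centroids
      cc <- as.integer(round(detections$col[i])) + 1L
      lab <- if (r >= 1L && cc >= 1L && r <= nrow(labels) &&
                 cc <= ncol(labels)) labels[r, cc] else 0L
      if (lab > 0L && !matched[lab]) {
        matched[lab] <- TRUE
        tp <- tp + 1L
      } else fp <- fp + 1L
    }
  }
  fn <- nTruth - tp
  f1 <- if (2L * tp + fp + fn == 0L) 1 else 2 * tp / (2 * tp + fp + fn)
  list(tp = tp, fp = fp, fn = fn, f1 = f1)
}
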