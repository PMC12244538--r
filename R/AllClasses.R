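# S4 classes for the central data objects. Run settings (HJWOA, CDL and
# generator configurations) are validated plain lists built by constructor
# functions; see hjwoaConfig(), cdlConfig(), tileGenParams(), tableGenParams().

#' HistologyTile: an RGB histology tile with optional ground-truth mask
#'
#' Pixels are stored as an H x W x 3 numeric array on the 0-255 scale
#' (row-major, origin top-left, 0-based semantics for reported coordinates).
#' The mask, when present, is an H x W matrix with 1 marking mitotic-figure
#' foreground.
#'
#' @slot pixels numeric H x W x 3 array, values in \[0, 255\].
#' @slot mask `NULL` or an H x W matrix with values in \{0, 1\}.
#' @slot id character identifier.
#' @slot splitTag character, one of `""`, `"train"`, `"val"`, `"test"`.
#' @export
setClass("HistologyTile",
  representation(pixels = "array", mask = "ANY", id = "character",
                 splitTag = "character"),
  prototype(mask = NULL, id = "tile", splitTag = ""))

setValidity("HistologyTile", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (anyNA(p) || min(p) < 0 || max(p) > 255)
    return("pixel values must lie in [0, 255]")
  m <- object@mask
  if (!is.null(m)) {
    if (!is.matrix(m) || !all(dim(m) == dim(p)[1:2]))
      return("mask must match the tile's spatial shape")
    if (!all(m %in% c(0, 1))) return("mask values must be 0 or 1")
  }
  if (!object@splitTag %in% c("", "train", "val", "test"))
    return("splitTag must be '', 'train', 'val' or 'test'")
  TRUE
})

#' StainProfile: H&E optical-density stain matrix and concentration scales
#'
#' @slot stainMatrix 2 x 3 matrix; rows are unit-norm, non-negative
#'   optical-density vectors for hematoxylin (row 1) and eosin (row 2).
#' @slot concentrationScale length-2 positive vector of robust (99th
#'   percentile) per-stain concentration maxima.
#' @slot backgroundIntensity per-channel background intensity (default 255).
#' @export
setClass("StainProfile",
  representation(stainMatrix = "matrix", concentrationScale = "numeric",
                 backgroundIntensity = "numeric"),
  prototype(backgroundIntensity = 255))

setValidity("StainProfile", function(object) {
  M <- object@stainMatrix
  if (!all(dim(M) == c(2L, 3L))) return("stainMatrix must be 2 x 3")
  if (any(M < -1e-9)) return("stainMatrix entries must be non-negative")
  nrm <- sqrt(rowSums(M^2))
  if (any(abs(nrm - 1) > 1e-6)) return("stainMatrix rows must be unit-norm")
  if (length(object@concentrationScale) != 2L ||
      any(object@concentrationScale <= 0))
    return("concentrationScale must be 2 positive values")
  if (any(object@backgroundIntensity <= 0))
    return("backgroundIntensity must be positive")
  TRUE
})

#' SplitSpec: train/validation/test partition settings
#'
#' @slot fractions length-3 non-negative vector (train, val, test) summing
#'   to 1 within 1e-9.
#' @slot seed integer seed (mandatory).
#' @slot stratify logical; preserve class proportions per split.
#' @export
setClass("SplitSpec",
  representation(fractions = "numeric", seed = "integer",
                 stratify = "logical"),
  prototype(fractions = c(0.7, 0.15, 0.15), stratify = TRUE))

setValidity("SplitSpec", function(object) {
  f <- object@fractions
  if (length(f) != 3L || any(f < 0)) return("fractions must be 3 values >= 0")
  if (abs(sum(f) - 1) > 1e-9) return("fractions must sum to 1 within 1e-9")
  if (length(object@seed) != 1L || is.na(object@seed))
    return("seed is mandatory")
  TRUE
})

#' FeatureRegistry: the ordered 150-slot feature registry
#'
#' Names and category tags (texture / shape / color) for every slot of the
#' feature vector, in extraction order. The default registry
#' ([defaultRegistry()]) has 86 texture, 42 shape and 22 color slots, so
#' category shares (57.3\% / 28\% / 14.7\%) fall inside the reported
#' 50-60\% / 25-30\% / 10-15\% bands.
#'
#' @slot slotNames character vector of unique slot names.
#' @slot categories character vector, one of "texture", "shape", "color".
#' @slot version character registry version string.
#' @export
setClass("FeatureRegistry",
  representation(slotNames = "character", categories = "character",
                 version = "character"),
  prototype(version = "1.0"))

setValidity("FeatureRegistry", function(object) {
  if (length(object@slotNames) != length(object@categories))
    return("slotNames and categories must align")
  if (anyDuplicated(object@slotNames)) return("slot names must be unique")
  if (!all(object@categories %in% c("texture", "shape", "color")))
    return("categories must be texture, shape or color")
  TRUE
})

#' FeatureVector: one tile's values over a registry
#'
#' @slot values numeric vector of finite values, one per registry slot.
#' @slot registry a [FeatureRegistry-class].
#' @slot label integer; `NA`, 0 (non-mitotic) or 1 (mitotic).
#' @export
setClass("FeatureVector",
  representation(values = "numeric", registry = "FeatureRegistry",
                 label = "integer"),
  prototype(label = NA_integer_))

setValidity("FeatureVector", function(object) {
  if (length(object@values) != length(object@registry@slotNames))
    return("values length must match the registry")
  if (!all(is.finite(object@values))) return("all values must be finite")
  if (!is.na(object@label) && !object@label %in% c(0L, 1L))
    return("label must be NA, 0 or 1")
  TRUE
})

#' SearchBounds: box constraints for the metaheuristic core
#'
#' @slot lb numeric lower bounds.
#' @slot ub numeric upper bounds, elementwise greater than `lb`.
#' @export
setClass("SearchBounds", representation(lb = "numeric", ub = "numeric"))

setValidity("SearchBounds", function(object) {
  if (length(object@lb) != length(object@ub) || !length(object@lb))
    return("lb and ub must be non-empty and of equal length")
  if (!all(object@lb < object@ub)) return("lb must be < ub elementwise")
  TRUE
})

#' SwarmState: population state of the swarm optimizers
#'
#' The core is a minimizer: `bestFitness` is the smallest objective value
#' evaluated so far and is monotone non-increasing under every public step.
#'
#' @slot positions n x d matrix of agent positions, inside bounds.
#' @slot fitnesses length-n vector of current agent objective values.
#' @slot bestPosition length-d best-ever position.
#' @slot bestFitness best-ever (minimum) objective value.
#' @slot t current iteration (0 after initialization).
#' @slot tMax total iteration budget (used by the time-control gate).
#' @slot bounds a [SearchBounds-class].
#' @slot rejected count of moves rejected for non-finite objective values.
#' @export
setClass("SwarmState",
  representation(positions = "matrix", fitnesses = "numeric",
                 bestPosition = "numeric", bestFitness = "numeric",
                 t = "integer", tMax = "integer", bounds = "SearchBounds",
                 rejected = "integer"),
  prototype(t = 0L, rejected = 0L))

setValidity("SwarmState", function(object) {
  n <- nrow(object@positions); d <- ncol(object@positions)
  if (n < 2L) return("at least 2 agents are required")
  if (length(object@fitnesses) != n) return("fitnesses must have one entry per agent")
  if (length(object@bestPosition) != d) return("bestPosition dimension mismatch")
  lb <- object@bounds@lb; ub <- object@bounds@ub
  if (length(lb) != d) return("bounds dimension mismatch")
  eps <- 1e-12
  if (any(t(object@positions) < lb - eps) || any(t(object@positions) > ub + eps))
    return("positions must lie inside bounds")
  if (object@tMax < 1L) return("tMax must be >= 1")
  TRUE
})

#' SelectionResult: outcome of a wrapper feature-selection run
#'
#' @slot mask integer 0/1 vector over candidate features.
#' @slot fitness best cross-validated F1 attained.
#' @slot history per-iteration best F1 (monotone non-decreasing).
#' @slot categoryShares named shares of the selected set per category.
#' @slot nSelected number of selected features.
#' @slot seed integer seed of the run.
#' @slot config the configuration list used.
#' @export
setClass("SelectionResult",
  representation(mask = "integer", fitness = "numeric", history = "numeric",
                 categoryShares = "numeric", nSelected = "integer",
                 seed = "integer", config = "list"))

setValidity("SelectionResult", function(object) {
  if (!all(object@mask %in% c(0L, 1L))) return("mask must be 0/1")
  if (object@fitness < 0 || object@fitness > 1) return("fitness must be in [0,1]")
  if (object@nSelected != sum(object@mask)) return("nSelected must equal sum(mask)")
  TRUE
})

#' ConfusionCounts: a 2 x 2 classification tally
#'
#' @slot tp,fp,tn,fn non-negative integer counts; at least one positive.
#' @export
setClass("ConfusionCounts",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@tn, object@fn)
  if (any(is.na(v)) || any(v < 0L)) return("counts must be non-negative")
  if (sum(v) < 1L) return("at least one count must be positive")
  TRUE
})

#' MetricReport: the eleven-metric evaluation suite plus precision
#'
#' Holds sensitivity, specificity, accuracy, precision, F-measure, critical
#' success index, balanced accuracy, Fowlkes-Mallows index, markedness,
#' negative likelihood ratio, and the false positive/negative rates. When a
#' metric's denominator is zero it is reported as the sentinel 0 and its name
#' recorded in `degenerate`; the arithmetic identities are only enforced for
#' non-degenerate metrics.
#'
#' @slot sen,spec,acc,precision,fMeasure,csi,ba,fmi,mk,nlr,fpr,fnr scalars.
#' @slot npv negative predictive value (used by markedness).
#' @slot degenerate character vector naming zero-denominator metrics.
#' @export
setClass("MetricReport",
  representation(sen = "numeric", spec = "numeric", acc = "numeric",
                 precision = "numeric", fMeasure = "numeric", csi = "numeric",
                 ba = "numeric", fmi = "numeric", mk = "numeric",
                 nlr = "numeric", fpr = "numeric", fnr = "numeric",
                 npv = "numeric", degenerate = "character"),
  prototype(degenerate = character(0)))

setValidity("MetricReport", function(object) {
  tol <- 1e-12
  deg <- object@degenerate
  ok <- function(nm) !any(nm %in% deg)
  if (ok(c("sen", "spec")) && abs(object@ba - (object@sen + object@spec) / 2) > tol)
    return("ba must equal (sen + spec)/2")
  if (ok("spec") && abs(object@fpr - (1 - object@spec)) > tol)
    return("fpr must equal 1 - spec")
  if (ok("sen") && abs(object@fnr - (1 - object@sen)) > tol)
    return("fnr must equal 1 - sen")
  if (ok(c("precision", "sen", "fmi")) &&
      abs(object@fmi - sqrt(object@precision * object@sen)) > tol)
    return("fmi must equal sqrt(precision * sen)")
  if (ok(c("precision", "npv", "mk")) &&
      abs(object@mk - (object@precision + object@npv - 1)) > tol)
    return("mk must equal precision + npv - 1")
  TRUE
})

#' TrainState: training history and the trained network
#'
#' @slot epoch last epoch run.
#' @slot bestValLoss smallest validation loss observed.
#' @slot epochsSinceImprovement epochs since `bestValLoss` last improved.
#' @slot history data.frame with per-epoch train loss, val loss and val F1.
#' @slot network the trained network specification (list).
#' @slot stoppedEarly logical.
#' @export
setClass("TrainState",
  representation(epoch = "integer", bestValLoss = "numeric",
                 epochsSinceImprovement = "integer", history = "data.frame",
                 network = "list", stoppedEarly = "logical"),
  prototype(stoppedEarly = FALSE))

# ---- show methods ---------------------------------------------------------

setMethod("show", "HistologyTile", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("HistologyTile '%s': %d x %d RGB%s%s\n", object@id, d[1], d[2],
              if (!is.null(object@mask))
                sprintf(", mask (%d fg px)", sum(object@mask)) else ", no mask",
              if (nzchar(object@splitTag))
                sprintf(" [%s]", object@splitTag) else ""))
})

setMethod("show", "StainProfile", function(object) {
  cat("StainProfile (rows: hematoxylin, eosin)\n")
  M <- round(object@stainMatrix, 3)
  dimnames(M) <- list(c("H", "E"), c("R", "G", "B"))
  print(M)
  cat("concentration scale:", sprintf("%.3f", object@concentrationScale), "\n")
})

setMethod("show", "FeatureRegistry", function(object) {
  tab <- table(factor(object@categories,
                      levels = c("texture", "shape", "color")))
  cat(sprintf("FeatureRegistry v%s: %d slots (%s)\n", object@version,
              length(object@slotNames),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "FeatureVector", function(object) {
  cat(sprintf("FeatureVector: %d slots, label %s\n", length(object@values),
              ifelse(is.na(object@label), "NA", object@label)))
})

setMethod("show", "SwarmState", function(object) {
  cat(sprintf("SwarmState: %d agents, %d dims, t = %d/%d, best = %.6g\n",
              nrow(object@positions), ncol(object@positions), object@t,
              object@tMax, object@bestFitness))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d features selected, F1 = %.4f (%d iterations)\n",
              object@nSelected, object@fitness, length(object@history)))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP %d  FP %d  TN %d  FN %d\n",
              object@tp, object@fp, object@tn, object@fn))
})

setMethod("show", "MetricReport", function(object) {
  v <- reportValues(object)
  cat("MetricReport\n")
  print(round(v, 4))
  if (length(object@degenerate))
    cat("degenerate (sentinel 0):",
        paste(object@degenerate, collapse = ", "), "\n")
})

# ---- accessors ------------------------------------------------------------

#' Accessors for HistologyTile
#'
#' @param x a [HistologyTile-class].
#' @return `tilePixels` the H x W x 3 array; `tileMask` the mask matrix or
#'   `NULL`; `tileId` the identifier.
#' @export
tilePixels <- function(x) { stopifnot(is(x, "HistologyTile")); x@pixels }

#' @rdname tilePixels
#' @export
tileMask <- function(x) { stopifnot(is(x, "HistologyTile")); x@mask }

#' @rdname tilePixels
#' @export
tileId <- function(x) { stopifnot(is(x, "HistologyTile")); x@id }

#' Accessors for SelectionResult
#'
#' @param x a [SelectionResult-class].
#' @return `selectedMask` the 0/1 vector; `selectionFitness` the best F1;
#'   `selectionHistory` the per-iteration best F1 trace.
#' @export
selectedMask <- function(x) { stopifnot(is(x, "SelectionResult")); x@mask }

#' @rdname selectedMask
#' @export
selectionFitness <- function(x) { stopifnot(is(x, "SelectionResult")); x@fitness }

#' @rdname selectedMask
#' @export
selectionHistory <- function(x) { stopifnot(is(x, "SelectionResult")); x@history }

#' Construct a HistologyTile
#'
#' @param pixels H x W x 3 numeric array on the 0-255 scale.
#' @param mask optional H x W 0/1 matrix marking mitotic foreground.
#' @param id identifier string.
#' @param splitTag optional split tag ("train", "val" or "test").
#' @return a validated [HistologyTile-class].
#' @export
#' @examples
#' t <- histologyTile(array(255, c(8, 8, 3)))
histologyTile <- function(pixels, mask = NULL, id = "tile", splitTag = "") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopShape("pixels must be an H x W x 3 array")
  if (is.array(mask) && length(dim(mask)) == 2L) mask <- as.matrix(mask)
  new("HistologyTile", pixels = pixels, mask = mask, id = as.character(id),
      splitTag = splitTag)
}

#' Construct a SplitSpec
#'
#' @param fractions length-3 vector (train, val, test) summing to 1.
#' @param seed integer seed (mandatory).
#' @param stratify logical; default `TRUE`.
#' @return a validated [SplitSpec-class].
#' @export
splitSpec <- function(fractions = c(0.7, 0.15, 0.15), seed, stratify = TRUE) {
  if (missing(seed)) stop("splitSpec: seed is mandatory")
  new("SplitSpec", fractions = as.numeric(fractions),
      seed = as.integer(seed), stratify = isTRUE(stratify))
}

#' Construct SearchBounds
#'
#' @param lb,ub numeric lower/upper bounds (recycled to a common length).
#' @param d optional dimension to recycle scalars to.
#' @return a validated [SearchBounds-class].
#' @export
searchBounds <- function(lb, ub, d = NULL) {
  if (!is.null(d)) { lb <- rep_len(lb, d); ub <- rep_len(ub, d) }
  n <- max(length(lb), length(ub))
  new("SearchBounds", lb = rep_len(as.numeric(lb), n),
      ub = rep_len(as.numeric(ub), n))
}
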