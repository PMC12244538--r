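# End-to-end orchestration: simulate -> normalize -> extract-features ->
# select-features -> train -> evaluate, with strict YAML configuration,
# derived per-stage seeds and a provenance manifest.

pipelineSchema <- function() {
  list(
    seed = "integer", outDir = "character", logLevel = "character",
    stages = list(simulate = "logical", normalize = "logical",
                  extractFeatures = "logical", selectFeatures = "logical",
                  train = "logical", evaluate = "logical"),
    simulate = list(nTrain = "integer", nVal = "integer", nTest = "integer",
                    side = "integer", nNuclei = "integer",
                    nMitotic = "integer", stainPerturbation = "numeric",
                    noiseSd = "numeric", difficulty = "character"),
    hjwoa = list(population = "integer", iterations = "integer",
                 crossoverRate = "numeric", mutationRate = "numeric",
                 kappa = "numeric", cvFolds = "integer",
                 stagnationPatience = "integer"),
    cdl = list(inputSide = "integer", widthScale = "numeric",
               focalAlpha = "numeric", focalGamma = "numeric",
               lrPretrained = "numeric", lrNew = "numeric",
               batchSize = "integer", maxEpochs = "integer",
               patience = "integer", dropout = "numeric", l2 = "numeric",
               pretrainedSource = "character"),
    detect = list(threshold = "numeric", minArea = "integer"))
}

defaultPipelineConfig <- function(seed = 1L, outDir = tempfile("mitoscope_run")) {
  list(seed = as.integer(seed), outDir = outDir, logLevel = "info",
       stages = list(simulate = TRUE, normalize = TRUE,
                     extractFeatures = TRUE, selectFeatures = TRUE,
                     train = TRUE, evaluate = TRUE),
       simulate = list(nTrain = 24L, nVal = 8L, nTest = 8L, side = 64L,
                       nNuclei = 10L, nMitotic = 2L,
                       stainPerturbation = 0.05, noiseSd = 2,
                       difficulty = "easy"),
       hjwoa = list(population = 50L, iterations = 100L,
                    crossoverRate = 0.8, mutationRate = 0.2, kappa = 0.5,
                    cvFolds = 3L, stagnationPatience = 15L),
       cdl = list(inputSide = 64L, widthScale = 0.25, focalAlpha = 0.25,
                  focalGamma = 2, lrPretrained = 1e-5, lrNew = 1e-3,
                  batchSize = 8L, maxEpochs = 100L, patience = 5L,
                  dropout = 0.3, l2 = 1e-4, pretrainedSource = "none"),
       detect = list(threshold = 0.5, minArea = 10L))
}

checkAgainstSchema <- function(x, schema, prefix = "") {
  bad <- character(0)
  for (key in names(x)) {
    full <- paste0(prefix, key)
    if (!key %in% names(schema)) {
      bad <- c(bad, full)
    } else if (is.list(schema[[key]]) && is.list(x[[key]])) {
      bad <- c(bad, checkAgainstSchema(x[[key]], schema[[key]],
                                       paste0(full, ".")))
    }
  }
  bad
}

#' Load or save a pipeline configuration (strict YAML)
#'
#' Unknown keys are errors (all offending keys are listed); missing keys
#' are filled from the defaults. An empty file is an error, never silent
#' defaults.
#'
#' @param path YAML file path.
#' @return `loadConfig` the validated configuration list; `saveConfig` the
#'   path, invisibly.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("loadConfig: no such file: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !length(raw))
    stop("loadConfig: empty configuration file: ", path)
  bad <- checkAgainstSchema(raw, pipelineSchema())
  if (length(bad))
    stop("loadConfig: unknown configuration key(s): ",
         paste(bad, collapse = ", "))
  if (is.null(raw$seed)) stop("loadConfig: seed is mandatory")
  cfg <- modifyList(defaultPipelineConfig(seed = raw$seed), raw)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname loadConfig
#' @param config a configuration list.
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

pipelineLog <- function(config, level, stage, msg, t0 = NULL) {
  if (identical(config$logLevel, "quiet")) return(invisible(NULL))
  rec <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              level = level, stage = stage, message = msg)
  if (!is.null(t0)) rec$elapsedSec <- round(as.numeric(Sys.time()) - t0, 2)
  message(jsonlite::toJSON(rec, auto_unbox = TRUE))
}

runStage <- function(config, stage, fn) {
  t0 <- as.numeric(Sys.time())
  pipelineLog(config, "info", stage, "start")
  out <- tryCatch(fn(), error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  pipelineLog(config, "info", stage, "done", t0)
  out
}

simulateTileSet <- function(n, params, seedBase, mitoticFraction = 0.5) {
  lapply(seq_len(n), function(i) {
    mitotic <- i <= round(n * mitoticFraction)
    p <- tileGenParams(side = params$side, nNuclei = params$nNuclei,
                       nMitotic = if (mitotic) params$nMitotic else 0L,
                       stainPerturbation = params$stainPerturbation,
                       noiseSd = params$noiseSd,
                       difficulty = params$difficulty,
                       seed = seedBase + i)
    genHETile(p)
  })
}

#' Run the full pipeline on synthetic data
#'
#' Executes the enabled stages in order — simulate, normalize,
#' extract-features, select-features, train, evaluate — writing stage
#' outputs, a consolidated metric report (`report.json`, all eleven metrics
#' plus the object-level detection score) and a provenance manifest
#' sufficient to re-execute the run. Any stage failure halts with the
#' failing stage named. One global seed deterministically derives all stage
#' seeds.
#'
#' @param config a configuration list from [loadConfig()] or
#'   [defaultPipelineConfig()].
#' @return the run directory path, invisibly; `report.json`,
#'   `provenance.json` and stage artifacts inside.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  st <- config$stages
  sim <- config$simulate
  tiles <- NULL
  if (isTRUE(st$simulate)) {
    tiles <- runStage(config, "simulate", function() {
      list(train = simulateTileSet(sim$nTrain, sim,
                                   deriveSeed(config$seed, "sim-train")),
           val = simulateTileSet(sim$nVal, sim,
                                 deriveSeed(config$seed, "sim-val")),
           test = simulateTileSet(sim$nTest, sim,
                                  deriveSeed(config$seed, "sim-test")))
    })
  } else {
    stop("pipeline dependency error: stage 'simulate' is disabled and no ",
         "external tile source is configured; run 'simulate' first")
  }
  tagSplit <- function(tl, tag) { tl@splitTag <- tag; tl }
  tiles$train <- lapply(tiles$train, tagSplit, "train")
  tiles$val <- lapply(tiles$val, tagSplit, "val")
  tiles$test <- lapply(tiles$test, tagSplit, "test")

  if (isTRUE(st$normalize)) {
    tiles <- runStage(config, "normalize", function() {
      ref <- selectReferenceTile(tiles$train)
      profile <- estimateStainProfile(ref)
      lapply(tiles, function(set) lapply(set, function(tl)
        preprocessTile(normalizeToReference(tl, profile),
                       side = config$cdl$inputSide)))
    })
  } else {
    tiles <- lapply(tiles, function(set) lapply(set, preprocessTile,
                                                side = config$cdl$inputSide))
  }

  registry <- defaultRegistry()
  featureTable <- NULL
  if (isTRUE(st$extractFeatures)) {
    featureTable <- runStage(config, "extract-features", function() {
      all <- c(tiles$train, tiles$val)
      labels <- vapply(all, function(tl) as.integer(sum(tl@mask) > 0),
                       integer(1))
      tab <- suppressMessages(extractFeatureTable(all, registry, labels))
      writeFeatureTable(tab, file.path(config$outDir, "features.csv"))
      tab
    })
  }

  selection <- NULL
  if (isTRUE(st$selectFeatures)) {
    if (is.null(featureTable))
      stop("pipeline dependency error: 'select-features' needs ",
           "'extract-features'; enable it first")
    selection <- runStage(config, "select-features", function() {
      X <- as.matrix(featureTable[, -(1:2)])
      y <- featureTable$label
      cfg <- hjwoaConfig(population = config$hjwoa$population,
                         iterations = config$hjwoa$iterations,
                         crossoverRate = config$hjwoa$crossoverRate,
                         mutationRate = config$hjwoa$mutationRate,
                         kappa = config$hjwoa$kappa,
                         cvFolds = config$hjwoa$cvFolds,
                         stagnationPatience = config$hjwoa$stagnationPatience,
                         seed = deriveSeed(config$seed, "select"))
      res <- hjwoaRun(X, y, registry, cfg)
      writeSelectionJSON(res, registry,
                         file.path(config$outDir, "selection.json"))
      res
    })
  }

  trainState <- NULL
  if (isTRUE(st$train)) {
    trainState <- runStage(config, "train", function() {
      cfg <- do.call(cdlConfig, c(config$cdl,
                                  list(seed = deriveSeed(config$seed,
                                                         "train"))))
      net <- buildCDL(cfg)
      net <- transferWeights(net, cfg$pretrainedSource)
      state <- trainCDL(net, tiles$train, tiles$val, cfg)
      saveCheckpoint(state@network,
                     file.path(config$outDir, "checkpoint.rds"),
                     registryVersion = registry@version)
      state
    })
  }

  report <- NULL
  if (isTRUE(st$evaluate)) {
    if (is.null(trainState))
      stop("pipeline dependency error: 'evaluate' needs 'train'; ",
           "enable it first")
    report <- runStage(config, "evaluate", function() {
      net <- trainState@network
      tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
      detTp <- 0L; detFp <- 0L; detFn <- 0L
      for (tile in tiles$test) {
        prob <- predictSegmentation(net, tile)
        pred <- (prob >= config$detect$threshold) + 0L
        tp <- tp + sum(pred == 1L & tile@mask == 1)
        fp <- fp + sum(pred == 1L & tile@mask == 0)
        tn <- tn + sum(pred == 0L & tile@mask == 0)
        fn <- fn + sum(pred == 0L & tile@mask == 1)
        det <- postprocessDetections(prob, config$detect$threshold,
                                     config$detect$minArea)
        sc <- scoreDetections(det, tile@mask)
        detTp <- detTp + sc$tp; detFp <- detFp + sc$fp; detFn <- detFn + sc$fn
      }
      rep <- metricSuite(confusionCounts(tp, fp, tn, fn))
      detF1 <- if (2 * detTp + detFp + detFn == 0) 1 else
        2 * detTp / (2 * detTp + detFp + detFn)
      writeMetricReportJSON(rep, file.path(config$outDir, "report.json"),
        extra = list(detectionF1 = detF1,
                     selection = if (is.null(selection)) "skipped" else
                       list(nSelected = selection@nSelected,
                            fitness = selection@fitness)))
      rep
    })
  }

  provenance <- list(
    package = "mitoscope",
    version = as.character(utils::packageVersion("mitoscope")),
    globalSeed = config$seed,
    stageSeeds = list(simTrain = deriveSeed(config$seed, "sim-train"),
                      simVal = deriveSeed(config$seed, "sim-val"),
                      simTest = deriveSeed(config$seed, "sim-test"),
                      select = deriveSeed(config$seed, "select"),
                      train = deriveSeed(config$seed, "train")),
    config = config)
  jsonlite::write_json(provenance,
                       file.path(config$outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$outDir)
}
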