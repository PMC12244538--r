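# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R generator, runs `expr`, and restores the caller's
#' `.Random.seed` so seeded package internals never disturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible stage seed from a global seed
#'
#' Folds the stage name into the global seed with a small string hash so each
#' pipeline stage gets an independent, reproducible stream. Result is kept
#' strictly below 2^31.
#'
#' @param globalSeed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
#' @examples
#' deriveSeed(1, "simulate")
deriveSeed <- function(globalSeed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(globalSeed) %% 2147483647 + h) %% 2147483563 + 1)
}

clampRange <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# sample() with deterministic size-1 behaviour (never the 1:n surprise)
sampleOne <- function(x) x[sample.int(length(x), 1L)]

# population-sd based skewness used by the shape aggregates
skewnessPop <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v < 1e-24) return(0)
  mean((x - m)^3) / v^1.5
}

# Shannon entropy (bits) of a count/probability vector
entropyBits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  p <- p / sum(p)
  -sum(p * log2(p))
}

stopShape <- function(msg) stop(structure(class = c("mitoscope_shape_error",
  "error", "condition"), list(message = msg, call = sys.call(-1))))
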