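# Swarm-metaheuristic core: jellyfish-search (JSO) update rules and the
# three walrus-optimization (WaOA) phases over a generic bounded continuous
# search space with greedy acceptance. The core minimizes; wrap a
# maximization objective as 1 - value (the feature selector does).
#
# Randomness conventions: R, rand and RI are fresh per-dimension draws; one
# time-control draw per agent per iteration, reused in that agent's
# passive/active gate. Non-finite objective values are treated as +Inf (the
# move is rejected and counted in state@rejected).

#' JSO parameters
#'
#' @param kappa time-control threshold, in (0, 1); default 0.5.
#' @param q0 chaotic-initialization seed in (0, 1), excluding the logistic
#'   map's fixed/periodic points \{0, 0.25, 0.5, 0.75, 1\}.
#' @param gammaCurrent factor multiplying the population-mean term of the
#'   ocean-current move (default 3).
#' @return validated parameter list of class `JSOParams`.
#' @export
jsoParams <- function(kappa = 0.5, q0 = 0.37, gammaCurrent = 3) {
  stopifnot(kappa > 0, kappa < 1)
  if (min(abs(q0 - c(0, 0.25, 0.5, 0.75, 1))) < 1e-9)
    stop("jsoParams: q0 must avoid the logistic map's fixed/periodic points",
         " {0, 0.25, 0.5, 0.75, 1}")
  stopifnot(q0 > 0, q0 < 1)
  structure(list(kappa = kappa, q0 = q0, gammaCurrent = gammaCurrent),
            class = "JSOParams")
}

#' Chaotic logistic-map initialization
#'
#' Iterates the logistic map y <- 4 y (1 - y) from `params$q0`, assigning
#' successive orbit values per agent and dimension (agent-major), then maps
#' \[0, 1\] affinely onto the bounds.
#'
#' @param n number of agents (>= 2).
#' @param bounds a [SearchBounds-class].
#' @param params a [jsoParams()] list.
#' @return n x d matrix of positions inside the bounds.
#' @export
#' @examples
#' chaoticInit(4, searchBounds(-1, 1, d = 3), jsoParams(q0 = 0.3))
chaoticInit <- function(n, bounds, params = jsoParams()) {
  stopifnot(n >= 2L, is(bounds, "SearchBounds"))
  validObject(bounds)
  d <- length(bounds@lb)
  y <- numeric(n * d)
  cur <- params$q0
  for (i in seq_len(n * d)) {
    cur <- 4 * cur * (1 - cur)
    y[i] <- cur
  }
  Y <- matrix(y, n, d, byrow = TRUE)
  sweep(sweep(Y, 2, bounds@ub - bounds@lb, `*`), 2, bounds@lb, `+`)
}

#' Time-control function
#'
#' TCF = |(1 - t/tMax) (2 rand - 1)| with rand ~ U(0, 1); always in
#' \[0, 1\] and exactly 0 at t = tMax.
#'
#' @param t current iteration, 0 <= t <= tMax.
#' @param tMax iteration budget, >= 1.
#' @return scalar in \[0, 1\].
#' @export
timeControl <- function(t, tMax) {
  stopifnot(t >= 0, t <= tMax, tMax >= 1)
  abs((1 - t / tMax) * (2 * runif(1) - 1))
}

#' Initialize a swarm
#'
#' @param n number of agents.
#' @param bounds a [SearchBounds-class].
#' @param objective function of a d-vector returning a finite scalar
#'   (minimized).
#' @param tMax iteration budget recorded in the state.
#' @param params a [jsoParams()] list (chaotic initialization seed).
#' @return a [SwarmState-class].
#' @export
initSwarm <- function(n, bounds, objective, tMax = 100L,
                      params = jsoParams()) {
  pos <- chaoticInit(n, bounds, params)
  fit <- apply(pos, 1, function(x) safeObjective(objective, x))
  best <- which.min(fit)
  new("SwarmState", positions = pos, fitnesses = fit,
      bestPosition = pos[best, ], bestFitness = fit[best], t = 0L,
      tMax = as.integer(tMax), bounds = bounds)
}

safeObjective <- function(objective, x) {
  v <- objective(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) Inf else v
}

# boundary wrap to the opposite limit (one pass), then clamp for steps
# exceeding a full range
wrapBounds <- function(x, lb, ub) {
  over <- x > ub
  under <- x < lb
  x[over] <- (x[over] - ub[over]) + lb[over]
  x[under] <- (x[under] - lb[under]) + ub[under]
  clampRange(x, lb, ub)
}

# greedy acceptance of one agent's trial; returns the updated state
acceptTrial <- function(state, j, trial, objective) {
  f <- safeObjective(objective, trial)
  if (!is.finite(f)) {
    state@rejected <- state@rejected + 1L
    return(state)
  }
  if (f < state@fitnesses[j]) {
    state@positions[j, ] <- trial
    state@fitnesses[j] <- f
  }
  if (f < state@bestFitness) {
    state@bestFitness <- f
    state@bestPosition <- trial
  }
  state
}

#' One jellyfish-search iteration
#'
#' Per agent: draw one time-control value; at or above `kappa` move with the
#' ocean current (toward the best position minus 3 R times the population
#' mean); otherwise move passively around the current position or actively
#' toward/away from a random partner depending on the fitness comparison.
#' Out-of-bounds coordinates wrap to the opposite limit; moves are accepted
#' greedily.
#'
#' @param state a [SwarmState-class].
#' @param params a [jsoParams()] list.
#' @param objective objective function (minimized).
#' @return the updated [SwarmState-class] with `t` advanced by 1.
#' @export
jsoStep <- function(state, params = jsoParams(), objective) {
  lb <- state@bounds@lb; ub <- state@bounds@ub
  d <- ncol(state@positions)
  tNow <- min(state@t + 1L, state@tMax)
  lambdaC <- colMeans(state@positions)
  for (j in seq_len(nrow(state@positions))) {
    tcf <- timeControl(tNow, state@tMax)
    Y <- state@positions[j, ]
    if (tcf >= params$kappa) {
      R <- runif(d)
      trial <- Y + R * (state@bestPosition - params$gammaCurrent * R * lambdaC)
    } else if (runif(1) > 1 - tcf) {
      trial <- Y + runif(d) * 0.1 * (ub - lb)  # passive (Type A)
    } else {
      i <- sampleOne(setdiff(seq_len(nrow(state@positions)), j))
      R <- runif(d)
      trial <- if (state@fitnesses[j] >= state@fitnesses[i])
        Y + R * (state@positions[i, ] - Y)   # partner fitter: approach
      else
        Y + R * (Y - state@positions[i, ])   # partner worse: retreat
    }
    state <- acceptTrial(state, j, wrapBounds(trial, lb, ub), objective)
  }
  state@t <- tNow
  state
}

#' WaOA feeding phase (exploration)
#'
#' Per agent and dimension: Z' = Z + (Wst - RI Z) rand with RI in \{1, 2\}
#' and rand ~ U(0, 1); positions are clamped to bounds and accepted greedily.
#'
#' @inheritParams jsoStep
#' @return the updated [SwarmState-class].
#' @export
waoaFeed <- function(state, objective) {
  lb <- state@bounds@lb; ub <- state@bounds@ub
  d <- ncol(state@positions)
  for (j in seq_len(nrow(state@positions))) {
    Z <- state@positions[j, ]
    RI <- sample(1:2, d, replace = TRUE)
    trial <- Z + (state@bestPosition - RI * Z) * runif(d)
    state <- acceptTrial(state, j, clampRange(trial, lb, ub), objective)
  }
  state
}

#' WaOA migration phase
#'
#' Per agent a random partner (never itself) is chosen; the agent moves
#' toward the partner when the partner is fitter, away otherwise, with
#' per-dimension rand and RI draws. Clamped to bounds, greedy acceptance.
#'
#' @inheritParams jsoStep
#' @return the updated [SwarmState-class].
#' @export
waoaMigrate <- function(state, objective) {
  n <- nrow(state@positions)
  stopifnot(n >= 2L)
  lb <- state@bounds@lb; ub <- state@bounds@ub
  d <- ncol(state@positions)
  for (j in seq_len(n)) {
    Z <- state@positions[j, ]
    l <- sampleOne(setdiff(seq_len(n), j))
    Zl <- state@positions[l, ]
    RI <- sample(1:2, d, replace = TRUE)
    rand <- runif(d)
    trial <- if (state@fitnesses[l] < state@fitnesses[j])
      Z + (Zl - RI * Z) * rand
    else
      Z + (Z - Zl) * rand
    state <- acceptTrial(state, j, clampRange(trial, lb, ub), objective)
  }
  state
}

#' WaOA escape/fight phase (local exploitation)
#'
#' Per agent, a perturbation drawn uniformly from a local neighborhood is
#' added. In `"shrinking"` mode (default) the neighborhood is the global box
#' scaled by 1/t and centered at zero offset, so it tightens as iterations
#' progress; in `"as_printed"` mode the local bounds equal the global
#' bounds, making the phase a global random restart.
#'
#' @inheritParams jsoStep
#' @param neighborhoodMode `"shrinking"` or `"as_printed"`.
#' @return the updated [SwarmState-class].
#' @export
waoaEscape <- function(state, objective,
                       neighborhoodMode = c("shrinking", "as_printed")) {
  neighborhoodMode <- match.arg(neighborhoodMode)
  lb <- state@bounds@lb; ub <- state@bounds@ub
  d <- ncol(state@positions)
  tNow <- max(1L, state@t)
  for (j in seq_len(nrow(state@positions))) {
    Z <- state@positions[j, ]
    if (neighborhoodMode == "shrinking") {
      half <- (ub - lb) / (2 * tNow)
      offset <- -half + (2 * half) * runif(d)
    } else {
      offset <- lb + (ub - lb) * runif(d)
    }
    state <- acceptTrial(state, j, clampRange(Z + offset, lb, ub), objective)
  }
  state
}

#' Run alternating JSO/WaOA iterations on an objective
#'
#' Reference driver used by the sanity benchmarks: odd iterations take a JSO
#' step, even iterations cycle the three WaOA phases.
#'
#' @param objective objective function (minimized).
#' @param bounds a [SearchBounds-class].
#' @param n population size.
#' @param iterations iteration budget.
#' @param seed integer seed.
#' @param params a [jsoParams()] list.
#' @return list with `best` (position), `bestFitness`, and `history`
#'   (best fitness per iteration).
#' @export
#' @examples
#' obj <- benchmarkObjective("sphere", 3)
#' runSwarm(obj$fn, searchBounds(-5, 5, d = 3), n = 20, iterations = 50,
#'          seed = 1)$bestFitness
runSwarm <- function(objective, bounds, n = 30L, iterations = 100L, seed,
                     params = jsoParams()) {
  if (missing(seed)) stop("runSwarm: seed is mandatory")
  withSeed(seed, {
    state <- initSwarm(n, bounds, objective, tMax = iterations, params)
    history <- numeric(iterations)
    phase <- 0L
    for (it in seq_len(iterations)) {
      if (it %% 2L == 1L) {
        state <- jsoStep(state, params, objective)
      } else {
        state <- switch(phase %% 3L + 1L,
                        waoaFeed(state, objective),
                        waoaMigrate(state, objective),
                        waoaEscape(state, objective))
        phase <- phase + 1L
        state@t <- min(state@t + 1L, state@tMax)
      }
      history[it] <- state@bestFitness
    }
    list(best = state@bestPosition, bestFitness = state@bestFitness,
         history = history, state = state)
  })
}
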