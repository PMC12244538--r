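# JSO update rules and WaOA phases over bounded continuous spaces.

test_that("chaotic initialization follows the logistic orbit into bounds", {
  # first iterate from 0.3 is 4 * 0.3 * 0.7 = 0.84
  b <- searchBounds(0, 1, d = 1)
  pos <- chaoticInit(2, b, jsoParams(q0 = 0.3))
  expect_equal(pos[1, 1], 0.84, tolerance = 1e-12)
  expect_equal(pos[2, 1], 4 * 0.84 * (1 - 0.84), tolerance = 1e-12)
  expect_error(jsoParams(q0 = 0.5), "fixed/periodic")
  expect_error(jsoParams(q0 = 0.75), "fixed/periodic")
  b5 <- searchBounds(-3, 7, d = 5)
  p <- chaoticInit(20, b5, jsoParams(q0 = 0.31))
  expect_true(all(p >= -3 & p <= 7))
})

test_that("the time-control gate stays in [0, 1] and dies at t = tMax", {
  set.seed(1)
  draws <- replicate(1e4, timeControl(sample(0:99, 1), 100))
  expect_true(all(draws >= 0 & draws <= 1))
  expect_identical(replicate(50, timeControl(100, 100)), rep(0, 50))
})

test_that("boundary wrap sends overshoot to the opposite limit", {
  lb <- c(0, 0); ub <- c(1, 1)
  expect_equal(mitoscope:::wrapBounds(c(1.2, -0.2), lb, ub), c(0.2, 0.8),
               tolerance = 1e-12)
  expect_equal(mitoscope:::wrapBounds(c(0.5, 1.0), lb, ub), c(0.5, 1.0))
})

test_that("greedy acceptance keeps the best fitness monotone on quadratics", {
  set.seed(5)
  for (rep in 1:4) {
    d <- sample(2:6, 1)
    ctr <- rnorm(d)
    obj <- function(x) sum((x - ctr)^2)
    bounds <- searchBounds(-5, 5, d = d)
    state <- initSwarm(10, bounds, obj, tMax = 100)
    prev <- state@bestFitness
    for (it in 1:25) {
      op <- it %% 4L
      state <- switch(op + 1L,
                      jsoStep(state, objective = obj),
                      waoaFeed(state, obj),
                      waoaMigrate(state, obj),
                      waoaEscape(state, obj))
      expect_lte(state@bestFitness, prev)
      prev <- state@bestFitness
      expect_true(all(t(state@positions) >= state@bounds@lb - 1e-12))
      expect_true(all(t(state@positions) <= state@bounds@ub + 1e-12))
      expect_true(all(state@fitnesses >= state@bestFitness))
    }
  }
})

test_that("agent fitnesses never increase under any phase", {
  set.seed(9)
  obj <- function(x) sum(abs(x))
  state <- initSwarm(8, searchBounds(-2, 2, d = 3), obj, tMax = 50)
  for (it in 1:10) {
    before <- state@fitnesses
    state <- waoaFeed(state, obj)
    expect_true(all(state@fitnesses <= before))
    before <- state@fitnesses
    state <- waoaMigrate(state, obj)
    expect_true(all(state@fitnesses <= before))
  }
})

test_that("the shrinking escape neighborhood tightens with iteration", {
  obj <- function(x) sum(x^2)
  set.seed(3)
  state <- initSwarm(10, searchBounds(-1, 1, d = 4), obj, tMax = 100)
  state@t <- 10L
  before <- state@positions
  state <- waoaEscape(state, obj, neighborhoodMode = "shrinking")
  # accepted moves are bounded by half the scaled box: (ub - lb)/(2 t)
  expect_lte(max(abs(state@positions - before)), 2 / (2 * 10) + 1e-12)
})

test_that("non-finite objective values reject the move and are counted", {
  set.seed(2)
  poison <- function(x) if (x[1] > 0) NaN else sum(x^2)
  state <- initSwarm(6, searchBounds(-1, 1, d = 2),
                     function(x) sum(x^2), tMax = 10)
  out <- waoaFeed(state, poison)
  expect_true(all(is.finite(out@fitnesses)))
  expect_gte(out@rejected, 0L)
  # a permanently-poisoned objective leaves every position unchanged
  out2 <- waoaFeed(state, function(x) Inf)
  expect_identical(out2@positions, state@positions)
  expect_gt(out2@rejected, 0L)
})

test_that("identical seeds reproduce trajectories bitwise", {
  obj <- benchmarkObjective("rastrigin", 4)
  a <- runSwarm(obj$fn, searchBounds(-5.12, 5.12, d = 4), n = 12,
                iterations = 30, seed = 77)
  b <- runSwarm(obj$fn, searchBounds(-5.12, 5.12, d = 4), n = 12,
                iterations = 30, seed = 77)
  expect_identical(a$state@positions, b$state@positions)
  expect_identical(a$history, b$history)
})

test_that("the escape phase in as-printed mode restarts globally", {
  set.seed(4)
  obj <- function(x) sum(x^2)
  state <- initSwarm(10, searchBounds(-1, 1, d = 3), obj, tMax = 100)
  state@t <- 50L
  out <- waoaEscape(state, obj, neighborhoodMode = "as_printed")
  expect_true(all(t(out@positions) >= -1 - 1e-12 &
                    t(out@positions) <= 1 + 1e-12))
})
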