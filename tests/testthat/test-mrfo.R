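test_that("initial populations respect bounds, size, and determinism", {
  p <- mrfoParams(nMax = 10, tMax = 5, seed = 7)
  set.seed(7); pop1 <- initPopulation(p, 15)
  set.seed(7); pop2 <- initPopulation(p, 15)
  expect_identical(solutions(pop1), solutions(pop2))
  expect_equal(dim(solutions(pop1)), c(10L, 15L))
  expect_true(all(solutions(pop1) >= 0 & solutions(pop1) <= 1))
  expect_true(all(is.na(scores(pop1))))
})

test_that("cyclone update matches hand-evaluated cases and clips", {
  p <- mrfoParams(nMax = 2, tMax = 10)
  # exploitation (t/tMax >= phase), i = 2: best + r (xPrev - xI) + beta (best - xI)
  out <- cycloneUpdate(0.2, 0.6, 0.9, list(r = 0.5, beta = 1, phase = 0.1),
                       i = 2, t = 5, params = p)
  expect_equal(out, 1.0)  # raw 1.8 clipped
  # exploration fixed point: reference pinned at the current position
  out <- cycloneUpdate(0.5, 0.3, 0.9,
                       list(r = 0.77, beta = -0.3, phase = 0.99, ref = 0.5),
                       i = 1, t = 1, params = p)
  expect_equal(out, 0.5)
  # population collapsed onto best is a fixed point of exploitation
  x <- rep(0.4, 5)
  out <- cycloneUpdate(x, x, x, list(r = 0.3, beta = 0.8, phase = 0),
                       i = 2, t = 10, params = p)
  expect_equal(out, x)
})

test_that("chain update matches hand-evaluated cases", {
  p <- mrfoParams()
  expect_equal(chainUpdate(0.2, 0.7, 0.8, list(r = 0.5, alpha = 0.5), i = 1, p), 0.8)
  expect_equal(chainUpdate(0.2, 0.7, 0.9, list(r = 1, alpha = 0), i = 1, p), 0.9)
  x <- rep(0.35, 4)
  expect_equal(chainUpdate(x, x, x, list(r = 0.9, alpha = 1.2), i = 2, p), x)
})

test_that("somersault update matches hand evaluation and fixed points", {
  p <- mrfoParams(somersault = 2)
  expect_equal(somersaultUpdate(0.4, 0.8, list(r2 = 0.5, r3 = 0.25), p), 1.0)
  x <- rep(0.6, 3)
  expect_equal(somersaultUpdate(x, x, list(r2 = 0.4, r3 = 0.4), p), x)
  expect_equal(somersaultUpdate(0.3, 0.9, list(r2 = 0, r3 = 0), p), 0.3)
})

test_that("a full population update matches a straight-line trace of the sweep", {
  # 1-D quadratic fitness, n = 2, every draw forced
  fit <- function(x) 1 - (x - 0.6)^2
  p <- mrfoParams(nMax = 2, tMax = 4, somersault = 2)
  sol <- matrix(c(0.2, 0.9), ncol = 1)
  pop <- new("MantaPopulation", solutions = sol,
             scores = c(fit(0.2), fit(0.9)),
             bestSolution = 0.9, bestScore = fit(0.9), iteration = 0L)
  forced <- list(
    list(branch = 0.7, r = 0.3, alpha = 0.15),                       # chain
    list(branch = 0.2, phase = 0.9, ref = 0.15, r = 0.6, beta = 0.4) # cyclone, explore
  )
  soms <- list(list(r2 = 0.2, r3 = 0.6), list(r2 = 0.9, r3 = 0.1))
  drawFun <- function(i, sweep, t, params, dimension)
    if (sweep == "foraging") forced[[i]] else soms[[i]]

  up <- updatePopulation(pop, fit, p, t = 2, drawFun = drawFun)

  # independent pencil-and-paper trace --------------------------------------
  # sort by score: f(0.9) = 0.91 > f(0.2) = 0.84, so order is (0.9, 0.2)
  x1 <- 0.9; x2 <- 0.2; best <- 0.9; bestSc <- fit(0.9)
  # member 1, chain, i = 1: x + r (best - x) + alpha (best - x) = 0.9
  x1 <- x1 + 0.3 * (best - x1) + 0.15 * (best - x1)
  # member 2, cyclone exploration (t/tMax = 0.5 < 0.9), i = 2:
  # ref + r (x1' - x2) + beta (ref - x2)
  x2 <- 0.15 + 0.6 * (x1 - x2) + 0.4 * (0.15 - x2)
  x2 <- min(1, max(0, x2))
  s1 <- fit(x1); if (s1 > bestSc) { bestSc <- s1; best <- x1 }
  s2 <- fit(x2); if (s2 > bestSc) { bestSc <- s2; best <- x2 }
  # somersault: x + S (r2 best - r3 x)
  x1 <- min(1, max(0, x1 + 2 * (0.2 * best - 0.6 * x1)))
  x2 <- min(1, max(0, x2 + 2 * (0.9 * best - 0.1 * x2)))
  s1 <- fit(x1); s2 <- fit(x2)
  if (s1 > bestSc) { bestSc <- s1; best <- x1 }
  if (s2 > bestSc) { bestSc <- s2; best <- x2 }

  expect_equal(as.vector(solutions(up$population)), c(x1, x2))
  expect_equal(scores(up$population), c(s1, s2))
  expect_equal(bestScore(up$population), bestSc)
  expect_equal(bestSolution(up$population), best)
})

test_that("constant fitness keeps the incumbent; best never worsens on any sweep", {
  p <- mrfoParams(nMax = 4, tMax = 3, seed = 5)
  set.seed(5)
  pop <- initPopulation(p, 3)
  pop@scores <- rep(0.5, 4); pop@bestScore <- 0.5
  pop@bestSolution <- pop@solutions[1, ]
  up <- updatePopulation(pop, function(x) 0.5, p, t = 1)
  expect_equal(bestScore(up$population), 0.5)
  expect_true(all(up$history$score == 0.5))

  set.seed(9)
  pop2 <- initPopulation(p, 3)
  f <- function(x) analyticFitness(x, centre = rep(0.4, 3))
  pop2@scores <- apply(pop2@solutions, 1, f)
  pop2@bestScore <- max(pop2@scores)
  pop2@bestSolution <- pop2@solutions[which.max(pop2@scores), ]
  before <- bestScore(pop2)
  up2 <- updatePopulation(pop2, f, p, t = 2)
  expect_gte(bestScore(up2$population), before)
  expect_true(all(diff(up2$history$bestScore) >= 0))
})

test_that("updates preserve [0,1] bounds under fuzzed draw sequences", {
  set.seed(31)
  p <- mrfoParams(nMax = 6, tMax = 8)
  f <- function(x) analyticFitness(x, centre = rep(0.7, 4))
  for (rep in 1:25) {
    pop <- initPopulation(p, 4)
    pop@scores <- apply(pop@solutions, 1, f)
    pop@bestScore <- max(pop@scores)
    pop@bestSolution <- pop@solutions[which.max(pop@scores), ]
    t <- sample(p$tMax, 1)
    up <- updatePopulation(pop, f, p, t = t)
    expect_true(all(solutions(up$population) >= 0 & solutions(up$population) <= 1))
  }
  # and under extreme forced draws
  wild <- function(i, sweep, t, params, dimension) {
    if (sweep == "foraging")
      list(branch = runif(1), phase = runif(1), ref = runif(dimension),
           r = runif(1, 0, 3), beta = runif(1, -4, 4), alpha = runif(1, 0, 3))
    else list(r2 = runif(1, 0, 2), r3 = runif(1, 0, 2))
  }
  pop <- initPopulation(p, 4)
  pop@scores <- apply(pop@solutions, 1, f)
  pop@bestScore <- max(pop@scores); pop@bestSolution <- pop@solutions[1, ]
  for (rep in 1:25) {
    up <- updatePopulation(pop, f, p, t = 3, drawFun = wild)
    pop <- up$population
    expect_true(all(solutions(pop) >= 0 & solutions(pop) <= 1))
  }
})

test_that("full runs are deterministic and keep a sound history", {
  f <- function(x) analyticFitness(x, centre = c(0.25, 0.75))
  p <- mrfoParams(nMax = 5, tMax = 6, seed = 123)
  r1 <- runMRFO(f, dimension = 2, params = p)
  r2 <- runMRFO(f, dimension = 2, params = p)
  expect_identical(history(r1), history(r2))
  expect_identical(bestSolution(r1), bestSolution(r2))
  h <- history(r1)
  expect_equal(nrow(h), 6 * 5 * 3)  # three scoring passes per member-iteration
  expect_true(all(diff(h$bestScore) >= 0))
  expect_setequal(unique(h$iteration), 1:6)
})

test_that("a failing fitness demotes the member instead of aborting the run", {
  flaky <- local({
    calls <- 0
    function(x) {
      calls <<- calls + 1
      if (calls == 3) stop("backend died")
      analyticFitness(x, centre = rep(0.5, 2))
    }
  })
  p <- mrfoParams(nMax = 2, tMax = 2, seed = 4)
  expect_warning(r <- runMRFO(flaky, dimension = 2, params = p),
                 "assigning worst score")
  expect_true(is.finite(bestScore(r)))
  expect_equal(sum(history(r)$score == -Inf), 1)
})

test_that("single-member, single-iteration degenerate run completes", {
  f <- function(x) analyticFitness(x, centre = rep(0.5, 15))
  r <- runMRFO(f, dimension = 15, params = mrfoParams(nMax = 1, tMax = 1, seed = 2))
  expect_length(bestSolution(r), 15)
  expect_true(all(bestSolution(r) >= 0 & bestSolution(r) <= 1))
  cfg <- decodeSolution(bestSolution(r))
  expect_s4_class(cfg, "DecodedConfig")
})

test_that("MRFO reaches the optimum of a 2-D sphere-type objective", {
  f <- function(x) analyticFitness(x, centre = c(0.3, 0.7))
  r <- runMRFO(f, dimension = 2, params = mrfoParams(nMax = 10, tMax = 50, seed = 1))
  # dense grid-search oracle on the same domain
  g <- seq(0, 1, length.out = 201)
  gridBest <- max(outer(g, g, Vectorize(function(a, b) f(c(a, b)))))
  expect_lt(gridBest - bestScore(r), 1e-2)
})
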