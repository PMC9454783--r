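#' MRFO run parameters
#'
#' Bundles the manta-ray foraging optimizer settings. Defaults follow the
#' published run configuration: population size 10, 10 iterations,
#' somersault factor `S = 2`, and search bounds `[0, 1]` (the encoded
#' hyperparameter hypercube).
#'
#' @param nMax population size (manta rays), >= 1
#' @param tMax iteration count, >= 1
#' @param somersault somersault factor `S` controlling the amplitude of the
#'   somersault flip around the incumbent best
#' @param lower,upper search-space bounds, `lower < upper`
#' @param seed optional integer seed for the run's random stream
#' @return a validated parameter list
#' @export
mrfoParams <- function(nMax = 10, tMax = 10, somersault = 2,
                       lower = 0, upper = 1, seed = NULL) {
  if (nMax < 1 || tMax < 1) stop("nMax and tMax must be >= 1", call. = FALSE)
  if (lower >= upper) stop("need lower < upper", call. = FALSE)
  if (somersault <= 0) stop("somersault factor must be > 0", call. = FALSE)
  list(nMax = as.integer(nMax), tMax = as.integer(tMax),
       somersault = somersault, lower = lower, upper = upper, seed = seed)
}

clipBounds <- function(x, params) pmin(params$upper, pmax(params$lower, x))

#' Chain and cyclone weight coefficients
#'
#' The weight coefficients of the foraging moves, in their standard MRFO
#' form: `alpha = 2 r sqrt(|log r|)` for chain foraging and
#' `beta = 2 exp(r1 (tMax - t + 1) / tMax) sin(2 pi r1)` for cyclone
#' foraging.
#'
#' @param r,r1 unit-interval draws
#' @param t current iteration; `tMax` total iterations
#' @param tMax iteration budget
#' @return numeric weight
#' @export
alphaWeight <- function(r) {
  ifelse(r <= 0, 0, 2 * r * sqrt(abs(log(r))))
}

#' @rdname alphaWeight
#' @export
betaWeight <- function(r1, t, tMax) {
  2 * exp(r1 * (tMax - t + 1) / tMax) * sin(2 * pi * r1)
}

#' Single-member foraging updates
#'
#' The three position-update rules applied to one manta ray, each followed
#' by clipping to the search bounds. `cycloneUpdate` spirals around a
#' reference point: a fresh uniform random point while exploring
#' (`phase > t/tMax`), the incumbent best while exploiting; the first-ranked
#' member (`i = 1`) spirals around the reference itself, later members chase
#' their predecessor `xPrev`. `chainUpdate` moves toward the best (for
#' `i = 1`) or the predecessor, plus an `alpha`-weighted pull to the best.
#' `somersaultUpdate` flips around the best position with amplitude set by
#' the somersault factor.
#'
#' All draws are passed explicitly through `draws` so sweeps can be forced
#' in tests; [updatePopulation()] generates them from the seeded run stream.
#'
#' @param xI current position of member `i`
#' @param xPrev position of member `i - 1` (already updated this sweep)
#' @param xBest incumbent best position
#' @param i member rank (1-based, in score-sorted order)
#' @param t,params iteration counter and [mrfoParams()] list
#' @param draws named list; cyclone uses `r`, `beta`, `phase`, `ref`
#'   (reference vector, exploration only); chain uses `r`, `alpha`;
#'   somersault uses `r2`, `r3`
#' @return updated position vector, inside bounds
#' @export
cycloneUpdate <- function(xI, xPrev, xBest, draws, i, t, params) {
  explore <- (t / params$tMax) < draws$phase
  ref <- if (explore) draws$ref else xBest
  lead <- if (i == 1) ref else xPrev
  out <- ref + draws$r * (lead - xI) + draws$beta * (ref - xI)
  clipBounds(out, params)
}

#' @rdname cycloneUpdate
#' @export
chainUpdate <- function(xI, xPrev, xBest, draws, i,
                        params = mrfoParams()) {
  lead <- if (i == 1) xBest else xPrev
  out <- xI + draws$r * (lead - xI) + draws$alpha * (xBest - xI)
  clipBounds(out, params)
}

#' @rdname cycloneUpdate
#' @export
somersaultUpdate <- function(xI, xBest, draws, params = mrfoParams()) {
  out <- xI + params$somersault * (draws$r2 * xBest - draws$r3 * xI)
  clipBounds(out, params)
}

#' Draw an initial random population
#'
#' Positions are element-wise uniform on `[lower, upper]`; scores start
#' unset (`NA`) and the incumbent best at `-Inf` until the first scoring
#' pass.
#'
#' @param params an [mrfoParams()] list
#' @param dimension encoded dimension (15 for the hyperparameter space)
#' @return a [MantaPopulation-class]
#' @export
initPopulation <- function(params, dimension) {
  sol <- matrix(stats::runif(params$nMax * dimension, params$lower, params$upper),
                nrow = params$nMax)
  new("MantaPopulation", solutions = sol,
      scores = rep(NA_real_, params$nMax),
      bestSolution = sol[1, ], bestScore = -Inf, iteration = 0L)
}

safeScore <- function(fitness, x, i) {
  s <- tryCatch(fitness(x), error = function(e) {
    warning(sprintf("fitness evaluation failed for member %d: %s; assigning worst score",
                    i, conditionMessage(e)), call. = FALSE)
    -Inf
  })
  if (!is.finite(s) && !identical(s, -Inf)) -Inf else s
}

defaultDraws <- function(i, sweep, t, params, dimension) {
  if (sweep == "foraging") {
    branch <- stats::runif(1)
    if (branch < 0.5) {
      phase <- stats::runif(1)
      ref <- if ((t / params$tMax) < phase)
        stats::runif(dimension, params$lower, params$upper) else NULL
      r <- stats::runif(1); r1 <- stats::runif(1)
      list(branch = branch, phase = phase, ref = ref, r = r,
           beta = betaWeight(r1, t, params$tMax))
    } else {
      r <- stats::runif(1)
      list(branch = branch, r = r, alpha = alphaWeight(r))
    }
  } else {
    list(r2 = stats::runif(1), r3 = stats::runif(1))
  }
}

#' One full MRFO population update (two sweeps plus re-evaluations)
#'
#' Executes one update of the whole population: sort members by score
#' (descending, ties by member index), extract the incumbent best, then
#' sweep 1 — per member branch on a fresh uniform draw (`< 0.5` cyclone,
#' else chain foraging), updating positions in place so each member chases
#' its already-updated predecessor — re-score everyone with greedy best
#' retention, sweep 2 — somersault every member — and re-score again. The
#' incumbent best never worsens.
#'
#' @param pop a scored [MantaPopulation-class]
#' @param fitness function mapping a position vector to a finite score
#'   (higher is better); evaluation errors demote the member to a sentinel
#'   worst score with a warning
#' @param params an [mrfoParams()] list
#' @param t current iteration (used by the cyclone explore/exploit gate)
#' @param drawFun optional `function(i, sweep, t, params, dimension)`
#'   returning the draw list for member `i` in sweep `"foraging"` or
#'   `"somersault"`; defaults to the seeded run stream
#' @return list with the updated population and a history data.frame of
#'   this update's evaluations
#' @export
updatePopulation <- function(pop, fitness, params, t, drawFun = NULL) {
  stopifnot(is(pop, "MantaPopulation"))
  if (anyNA(pop@scores)) stop("population must be fully scored before updating", call. = FALSE)
  if (is.null(drawFun)) drawFun <- defaultDraws
  dimension <- ncol(pop@solutions)
  n <- nrow(pop@solutions)

  ord <- order(-pop@scores, seq_len(n))
  sol <- pop@solutions[ord, , drop = FALSE]
  sc <- pop@scores[ord]
  best <- sol[1, ]; bestSc <- sc[1]
  if (pop@bestScore > bestSc) { best <- pop@bestSolution; bestSc <- pop@bestScore }

  hist <- list()
  for (i in seq_len(n)) {
    d <- drawFun(i, "foraging", t, params, dimension)
    xPrev <- if (i > 1) sol[i - 1, ] else sol[i, ]
    sol[i, ] <- if (d$branch < 0.5)
      cycloneUpdate(sol[i, ], xPrev, best, d, i, t, params)
    else
      chainUpdate(sol[i, ], xPrev, best, d, i, params)
  }
  for (i in seq_len(n)) {
    sc[i] <- safeScore(fitness, sol[i, ], i)
    if (sc[i] > bestSc) { bestSc <- sc[i]; best <- sol[i, ] }
    hist[[length(hist) + 1]] <- data.frame(
      iteration = t, member = i, sweep = "foraging",
      score = sc[i], bestScore = bestSc)
  }
  for (i in seq_len(n)) {
    d <- drawFun(i, "somersault", t, params, dimension)
    sol[i, ] <- somersaultUpdate(sol[i, ], best, d, params)
  }
  for (i in seq_len(n)) {
    sc[i] <- safeScore(fitness, sol[i, ], i)
    if (sc[i] > bestSc) { bestSc <- sc[i]; best <- sol[i, ] }
    hist[[length(hist) + 1]] <- data.frame(
      iteration = t, member = i, sweep = "somersault",
      score = sc[i], bestScore = bestSc)
  }

  newPop <- new("MantaPopulation", solutions = sol, scores = sc,
                bestSolution = best, bestScore = bestSc, iteration = as.integer(t))
  list(population = newPop, history = do.call(rbind, hist))
}

#' Run the full MRFO optimization loop
#'
#' Initializes a random population, then for `tMax` iterations scores every
#' member and applies [updatePopulation()]. Each iteration therefore costs
#' about three fitness evaluations per member (initial scoring plus the two
#' in-sweep re-evaluations); wrap an expensive objective with
#' [makeTransferFitness()] or your own memoization to avoid retraining
#' identical configurations.
#'
#' @param fitness objective function over position vectors, higher is better
#' @param dimension search dimension (15 for the encoded hyperparameter
#'   space; ignored when `space` is given)
#' @param params an [mrfoParams()] list; `params$seed` seeds the run
#' @param space optional [HyperparameterSpace-class]; fixes `dimension = 15`
#' @param verbose print the per-iteration incumbent best
#' @return an [MRFORun-class] with the best position, best score, and a
#'   per-evaluation history
#' @export
runMRFO <- function(fitness, dimension = 15L, params = mrfoParams(),
                    space = NULL, verbose = FALSE) {
  if (!is.null(space)) {
    stopifnot(is(space, "HyperparameterSpace"))
    dimension <- 15L
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  pop <- initPopulation(params, dimension)
  hist <- list()
  best <- pop@bestSolution; bestSc <- -Inf
  for (t in seq_len(params$tMax)) {
    sc <- pop@scores
    for (i in seq_len(params$nMax)) {
      sc[i] <- safeScore(fitness, pop@solutions[i, ], i)
      if (sc[i] > bestSc) { bestSc <- sc[i]; best <- pop@solutions[i, ] }
      hist[[length(hist) + 1]] <- data.frame(
        iteration = t, member = i, sweep = "initial",
        score = sc[i], bestScore = bestSc)
    }
    pop@scores <- sc
    if (bestSc > pop@bestScore) { pop@bestScore <- bestSc; pop@bestSolution <- best }
    up <- updatePopulation(pop, fitness, params, t)
    pop <- up$population
    hist[[length(hist) + 1]] <- up$history
    best <- pop@bestSolution; bestSc <- pop@bestScore
    if (verbose)
      message(sprintf("iteration %d/%d: best score %.6f", t, params$tMax, bestSc))
  }
  new("MRFORun", bestSolution = best, bestScore = bestSc,
      history = do.call(rbind, hist), params = params)
}

#' @rdname accessors
setMethod("bestSolution", "MantaPopulation", function(x) x@bestSolution)
#' @rdname accessors
setMethod("bestScore", "MantaPopulation", function(x) x@bestScore)
#' @rdname accessors
setMethod("solutions", "MantaPopulation", function(x) x@solutions)
#' @rdname accessors
setMethod("scores", "MantaPopulation", function(x) x@scores)
#' @rdname accessors
setMethod("bestSolution", "MRFORun", function(x) x@bestSolution)
#' @rdname accessors
setMethod("bestScore", "MRFORun", function(x) x@bestScore)
#' @rdname accessors
setMethod("history", "MRFORun", function(x) x@history)

#' @describeIn MantaPopulation-class population summary
#' @param object a `MantaPopulation`
#' @export
setMethod("show", "MantaPopulation", function(object) {
  cat(sprintf("MantaPopulation: %d members, dimension %d, iteration %d\n",
              nrow(object@solutions), ncol(object@solutions), object@iteration))
  cat(sprintf("  best score: %s\n",
              if (is.finite(object@bestScore)) format(object@bestScore) else "unscored"))
})

#' @describeIn MRFORun-class run summary
#' @param object an `MRFORun`
#' @export
setMethod("show", "MRFORun", function(object) {
  cat(sprintf("MRFORun: %d iterations x %d members, %d evaluations\n",
              object@params$tMax, object@params$nMax, nrow(object@history)))
  cat(sprintf("  best score: %.6f\n", object@bestScore))
})

#' Write an optimization history to CSV
#'
#' One row per fitness evaluation: iteration, member, sweep, score, and the
#' incumbent best at that point.
#'
#' @param run an [MRFORun-class]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeHistory <- function(run, path) {
  utils::write.csv(history(run), path, row.names = FALSE)
  invisible(path)
}
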