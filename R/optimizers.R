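#' @include AllClasses.R AllGenerics.R weighting.R
NULL

#' Optimizer configuration
#'
#' Shared configuration for the two population metaheuristics. The
#' published pipeline reports no optimizer hyperparameters, so the defaults
#' follow the algorithms' standard reference settings: population 30 and
#' 100 iterations; PSO with inertia decaying linearly from 0.9 to 0.4,
#' cognitive and social constants c1 = c2 = 2 and velocities clamped to
#' 0.2 x the search range; ALO with the standard boundary-shrink exponent
#' schedule (w = 2, 3, 4, 5, 6 once the iteration fraction exceeds 0.1,
#' 0.5, 0.75, 0.9, 0.95).
#'
#' @param populationSize number of particles / ants (>= 2).
#' @param maxIterations iteration budget (>= 1).
#' @param inertiaStart,inertiaEnd linear inertia schedule endpoints (PSO).
#' @param cognitive,social acceleration constants c1, c2 > 0 (PSO).
#' @param velocityClampFraction velocity clamp as a fraction of the
#'   per-dimension range (PSO).
#' @param aloSchedule named numeric vector mapping iteration-fraction
#'   thresholds to shrink exponents w (ALO).
#' @return a list of class "OptimizerConfig".
#' @export
optimControl <- function(populationSize = 30L, maxIterations = 100L,
                         inertiaStart = 0.9, inertiaEnd = 0.4,
                         cognitive = 2, social = 2,
                         velocityClampFraction = 0.2,
                         aloSchedule = c("0.1" = 2, "0.5" = 3, "0.75" = 4,
                                         "0.9" = 5, "0.95" = 6)) {
  stopifnot(populationSize >= 2, maxIterations >= 1,
            cognitive > 0, social > 0, velocityClampFraction > 0)
  structure(list(populationSize = as.integer(populationSize),
                 maxIterations = as.integer(maxIterations),
                 inertiaStart = inertiaStart, inertiaEnd = inertiaEnd,
                 cognitive = cognitive, social = social,
                 velocityClampFraction = velocityClampFraction,
                 aloSchedule = aloSchedule),
            class = "OptimizerConfig")
}

# resolve the objective: either a plain function(x) -> numeric, or a
# FitnessEvaluator (then d defaults to its feature count)
.resolveObjective <- function(fn, d) {
  if (is(fn, "FitnessEvaluator")) {
    ev <- fn
    if (is.null(d)) d <- ncol(ev@values)
    list(fn = function(w) evaluateFitness(w, ev), d = d)
  } else {
    stopifnot(is.function(fn), !is.null(d))
    list(fn = fn, d = as.integer(d))
  }
}

.initPopulation <- function(pop, d, init) {
  x <- matrix(stats::runif(pop * d), pop, d)
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    take <- min(nrow(init), pop)
    x[seq_len(take), ] <- .clip(init[seq_len(take), , drop = FALSE], 0, 1)
  }
  x
}

#' Particle swarm optimization over [0, 1]^d
#'
#' Maximizes the objective with the canonical PSO update: each particle's
#' velocity is pulled toward its personal best and the global best,
#' \code{v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)}, with linearly
#' decaying inertia, velocity clamping and positions clipped to the unit
#' box. The global best is never lost, so the best-fitness history is
#' non-decreasing. Deterministic given \code{seed}.
#'
#' @param fn objective to maximize: a function(numeric(d)) -> numeric, or a
#'   \linkS4class{FitnessEvaluator}.
#' @param d dimension of the search space (taken from the evaluator when
#'   omitted).
#' @param control an \code{\link{optimControl}}.
#' @param seed integer seed.
#' @param init optional matrix (or vector) of candidate positions injected
#'   into the initial population — e.g. the all-ones weight vector, which
#'   guarantees the result is at least as fit as the unweighted baseline.
#' @return an \linkS4class{OptimizationResult}.
#' @export
#' @examples
#' res <- psoOptimize(function(x) -sum((x - 0.5)^2), d = 3,
#'                    control = optimControl(10, 25), seed = 1)
#' bestWeights(res)
psoOptimize <- function(fn, d = NULL, control = optimControl(), seed = 1L,
                        init = NULL) {
  obj <- .resolveObjective(fn, d)
  fn <- obj$fn; d <- obj$d
  pop <- control$populationSize
  iters <- control$maxIterations
  vmax <- control$velocityClampFraction
  evals <- 0L
  withr::with_seed(seed, {
    x <- .initPopulation(pop, d, init)
    v <- matrix(stats::runif(pop * d, -vmax, vmax), pop, d)
    f <- apply(x, 1, fn); evals <- evals + pop
    pbest <- x; pbestF <- f
    gi <- which.max(f)
    gbest <- x[gi, ]; gbestF <- f[gi]
    history <- gbestF
    for (t in seq_len(iters)) {
      w <- control$inertiaStart -
        (control$inertiaStart - control$inertiaEnd) * t / iters
      r1 <- matrix(stats::runif(pop * d), pop, d)
      r2 <- matrix(stats::runif(pop * d), pop, d)
      v <- w * v + control$cognitive * r1 * (pbest - x) +
        control$social * r2 * (matrix(gbest, pop, d, byrow = TRUE) - x)
      v <- .clip(v, -vmax, vmax)
      x <- .clip(x + v, 0, 1)
      f <- apply(x, 1, fn); evals <- evals + pop
      imp <- f > pbestF
      pbest[imp, ] <- x[imp, ]
      pbestF[imp] <- f[imp]
      if (max(pbestF) > gbestF) {
        gi <- which.max(pbestF)
        gbest <- pbest[gi, ]; gbestF <- pbestF[gi]
      }
      history <- c(history, gbestF)
    }
  })
  new("OptimizationResult", method = "pso", bestWeights = as.numeric(gbest),
      bestFitness = gbestF, fitnessHistory = history,
      evaluations = evals, seed = as.integer(seed))
}

#' One bounded random walk of the ant lion scheme
#'
#' Generates the cumulative sum of \code{nSteps} random unit steps
#' (step = 2*[r > 0.5] - 1 with r ~ U(0,1)) starting at 0, then min-max
#' rescales each position into [lower, upper]. After rescaling, a
#' non-constant walk attains the lower bound at its minimum and the upper
#' bound at its maximum; a degenerate interval (lower = upper) gives a
#' constant walk at that value. Uses the current RNG stream.
#'
#' @param nSteps number of steps (>= 1).
#' @param lower,upper interval bounds.
#' @return numeric vector of length \code{nSteps + 1}.
#' @export
aloRandomWalk <- function(nSteps, lower = 0, upper = 1) {
  stopifnot(nSteps >= 1, lower <= upper)
  steps <- ifelse(stats::runif(nSteps) > 0.5, 1, -1)
  walk <- cumsum(c(0, steps))
  span <- max(walk) - min(walk)
  if (span == 0 || upper == lower) return(rep((lower + upper) / 2, nSteps + 1))
  (walk - min(walk)) / span * (upper - lower) + lower
}

# shrink ratio I at iteration t of T per the exponent schedule
.aloShrinkRatio <- function(t, T_, schedule) {
  fr <- t / T_
  thresholds <- as.numeric(names(schedule))
  hit <- which(fr > thresholds)
  if (!length(hit)) return(1)
  10^schedule[[max(hit)]] * fr
}

# one rescaled random walk around a focal antlion: the unit bounds are
# shrunk by I and shifted to the antlion with random sign, and the walk's
# position at iteration t is taken
.aloWalkAround <- function(focal, t, T_, I, d) {
  lb <- rep(0, d) / I; ub <- rep(1, d) / I
  lb <- if (stats::runif(1) < 0.5) lb + focal else -lb + focal
  ub <- if (stats::runif(1) < 0.5) ub + focal else -ub + focal
  lo <- pmin(lb, ub); hi <- pmax(lb, ub)
  vapply(seq_len(d), function(j) aloRandomWalk(T_, lo[j], hi[j])[t + 1],
         numeric(1))
}

#' Ant lion optimization over [0, 1]^d
#'
#' Maximizes the objective with the ant-lion hunting scheme: ants perform
#' bounded random walks whose intervals shrink over iterations (ratio
#' \code{I = 10^w * t/T} per the exponent schedule) and are centred with
#' random sign on a roulette-selected ant lion and on the elite (best) ant
#' lion; each ant's new position is the average of the two walks, clipped
#' to the unit box. An ant lion is replaced by an ant that becomes fitter
#' ("catching prey"), and the elite — never lost — is updated whenever a
#' fitter ant lion appears, so the best-fitness history is non-decreasing.
#' Roulette selection uses min-shifted fitness values; when all are equal
#' it falls back to uniform selection. Deterministic given \code{seed}.
#'
#' @inheritParams psoOptimize
#' @return an \linkS4class{OptimizationResult}.
#' @export
#' @examples
#' res <- aloOptimize(function(x) -sum((x - 0.5)^2), d = 3,
#'                    control = optimControl(10, 25), seed = 1)
#' bestFitness(res)
aloOptimize <- function(fn, d = NULL, control = optimControl(), seed = 1L,
                        init = NULL) {
  obj <- .resolveObjective(fn, d)
  fn <- obj$fn; d <- obj$d
  pop <- control$populationSize
  iters <- control$maxIterations
  schedule <- control$aloSchedule
  evals <- 0L
  withr::with_seed(seed, {
    antlions <- .initPopulation(pop, d, init)
    fit <- apply(antlions, 1, fn); evals <- evals + pop
    ei <- which.max(fit)
    elite <- antlions[ei, ]; eliteF <- fit[ei]
    history <- eliteF
    for (t in seq_len(iters)) {
      I <- .aloShrinkRatio(t, iters, schedule)
      probs <- fit - min(fit)
      if (sum(probs) == 0) probs <- rep(1, pop)
      for (i in seq_len(pop)) {
        sel <- sample.int(pop, 1, prob = probs)
        ant <- (.aloWalkAround(antlions[sel, ], t, iters, I, d) +
                .aloWalkAround(elite, t, iters, I, d)) / 2
        ant <- .clip(ant, 0, 1)
        fa <- fn(ant); evals <- evals + 1L
        if (fa > fit[i]) {          # the ant is caught: antlion takes its place
          antlions[i, ] <- ant
          fit[i] <- fa
        }
      }
      if (max(fit) > eliteF) {
        ei <- which.max(fit)
        elite <- antlions[ei, ]; eliteF <- fit[ei]
      }
      history <- c(history, eliteF)
    }
  })
  new("OptimizationResult", method = "alo",
      bestWeights = as.numeric(elite), bestFitness = eliteF,
      fitnessHistory = history, evaluations = evals,
      seed = as.integer(seed))
}

#' Accessors for optimization results
#'
#' @param x an \linkS4class{OptimizationResult}.
#' @name optimizers
NULL

#' @rdname optimizers
#' @export
setMethod("bestWeights", "OptimizationResult", function(x) x@bestWeights)

#' @rdname optimizers
#' @export
setMethod("bestFitness", "OptimizationResult", function(x) x@bestFitness)

#' @rdname optimizers
#' @export
setMethod("fitnessHistory", "OptimizationResult", function(x) x@fitnessHistory)

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf("OptimizationResult (%s): best fitness %.4f after %d evaluations\n",
              object@method, object@bestFitness, object@evaluations))
  cat(sprintf("  best weights: %s\n",
              paste(sprintf("%.3f", object@bestWeights), collapse = ", ")))
})
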