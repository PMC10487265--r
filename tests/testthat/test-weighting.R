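evaluatorFixture <- function(nPerClass = 20, seed = 31, k = 3) {
  ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = nPerClass,
                                                  nInformative = 3,
                                                  nNoise = 7,
                                                  classSeparation = 4,
                                                  seed = seed))
  fitnessEvaluator(ft, k = k, seed = seed)
}

test_that("fitness is a pure function of the weights on frozen folds", {
  ev <- evaluatorFixture()
  w <- rep(0.7, 10)
  f1 <- evaluateFitness(w, ev)
  f2 <- evaluateFitness(w, ev)
  expect_identical(f1, f2)
  expect_true(f1 >= 0 && f1 <= 1)
  expect_error(evaluateFitness(rep(1, 4), ev), "length")
})

test_that("identity weights reproduce the unweighted accuracy; zero weights give chance", {
  ev <- evaluatorFixture()
  ones <- evaluateFitness(rep(1, 10), ev)
  expect_gt(ones, 3 / 7)   # well above chance on separation-4 tables

  # identity weighting equals an independently coded unweighted CV on the
  # evaluator's own frozen folds
  x <- ev@values; y <- ev@labels
  accs <- vapply(sort(unique(ev@folds)), function(kk) {
    tr <- ev@folds != kk
    mu <- colMeans(x[tr, ]); sd_ <- apply(x[tr, ], 2, sd)
    zt <- sweep(sweep(x[tr, ], 2, mu), 2, sd_, "/")
    zv <- sweep(sweep(x[!tr, ], 2, mu), 2, sd_, "/")
    fit <- e1071::svm(zt, y[tr], kernel = "polynomial", degree = 3,
                      cost = 1, gamma = 1 / ncol(x), coef0 = 0, scale = FALSE)
    mean(predict(fit, zv) == y[!tr])
  }, numeric(1))
  expect_equal(ones, mean(accs), tolerance = 1e-12)

  # all-zero weights erase every feature: the classifier can do no better
  # than majority/chance behaviour on the balanced 7-class design
  zeros <- evaluateFitness(rep(0, 10), ev)
  expect_lt(abs(zeros - 1 / 7), 0.05)

  # permuted labels: any weighting sits at chance
  ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 20, seed = 77))
  permLabels <- withr::with_seed(1, sample(cellLabels(ft)))
  evPerm <- fitnessEvaluator(featureMatrix(ft), permLabels, k = 3, seed = 7)
  expect_lt(abs(evaluateFitness(rep(1, 10), evPerm) - 1 / 7), 0.08)
})

test_that("weight application scales columns and preserves provenance", {
  ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 5, seed = 2))
  w <- c(0.5, rep(1, 8), 0)
  wt <- applyWeights(ft, w)
  expect_equal(featureMatrix(wt)[, 1], featureMatrix(ft)[, 1] * 0.5)
  expect_true(all(featureMatrix(wt)[, 10] == 0))
  expect_equal(featureMatrix(applyWeights(ft, rep(1, 10))),
               featureMatrix(ft))
  expect_identical(featureProvenance(wt), featureProvenance(ft))
  expect_error(applyWeights(ft, rep(1, 3)), "length")
})

test_that("both optimizers find the concave quadratic optimum", {
  fn <- function(x) -sum((x - 0.5)^2)
  ctrl <- optimControl(populationSize = 20, maxIterations = 100)
  for (opt in list(psoOptimize, aloOptimize)) {
    res <- opt(fn, d = 5, control = ctrl, seed = 3)
    expect_true(all(abs(bestWeights(res) - 0.5) < 0.05))
    expect_equal(bestFitness(res), fn(bestWeights(res)))
  }
})

test_that("optimization is deterministic and elitist with bounded budget", {
  fn <- function(x) -sum((x - 0.3)^2)
  ctrl <- optimControl(populationSize = 8, maxIterations = 15)
  for (opt in list(psoOptimize, aloOptimize)) {
    a <- opt(fn, d = 4, control = ctrl, seed = 9)
    b <- opt(fn, d = 4, control = ctrl, seed = 9)
    expect_identical(bestWeights(a), bestWeights(b))
    expect_identical(fitnessHistory(a), fitnessHistory(b))
    expect_true(all(diff(fitnessHistory(a)) >= 0))
    expect_length(fitnessHistory(a), 16)
    expect_lte(a@evaluations, 8 * 16)
    expect_true(all(bestWeights(a) >= 0 & bestWeights(a) <= 1))
  }
})

test_that("a constant objective leaves the initial best untouched", {
  fn <- function(x) 0.5
  ctrl <- optimControl(populationSize = 6, maxIterations = 10)
  for (opt in list(psoOptimize, aloOptimize)) {
    res <- opt(fn, d = 3, control = ctrl, seed = 2)
    expect_true(all(fitnessHistory(res) == 0.5))
  }
})

test_that("injected candidates join the initial population", {
  # an injected optimum is never lost (elitism), even with a tiny budget
  fn <- function(x) -sum((x - 0.5)^2)
  ctrl <- optimControl(populationSize = 5, maxIterations = 2)
  for (opt in list(psoOptimize, aloOptimize)) {
    res <- opt(fn, d = 4, control = ctrl, seed = 1, init = rep(0.5, 4))
    expect_gte(bestFitness(res), fn(rep(0.5, 4)))
  }
})

test_that("the bounded random walk rescales into the requested interval", {
  # min-max identity after rescaling
  w <- withr::with_seed(1, aloRandomWalk(50, 0.2, 0.8))
  expect_length(w, 51)
  expect_equal(min(w), 0.2)
  expect_equal(max(w), 0.8)

  # degenerate interval gives a constant walk
  w0 <- withr::with_seed(1, aloRandomWalk(20, 0, 0))
  expect_true(all(w0 == 0))

  # raw +/-1 cumulative sums have SD ~ sqrt(t) (Monte Carlo on the
  # unscaled walk distribution)
  t_ <- 64
  finals <- withr::with_seed(4, replicate(10000, {
    sum(ifelse(runif(t_) > 0.5, 1, -1))
  }))
  expect_lt(abs(sd(finals) - sqrt(t_)) / sqrt(t_), 0.05)
})

test_that("a single-antlion-like degenerate population still improves the elite", {
  fn <- function(x) -sum((x - 0.4)^2)
  # population of two identical points: roulette is uniform over equals
  res <- aloOptimize(fn, d = 3,
                     control = optimControl(populationSize = 2,
                                            maxIterations = 30),
                     seed = 6, init = rbind(rep(0.9, 3), rep(0.9, 3)))
  expect_gt(bestFitness(res), fn(rep(0.9, 3)))
  expect_true(all(diff(fitnessHistory(res)) >= 0))
})

test_that("learned weights favour informative over noise columns", {
  # one representative seed per optimizer here (the multi-seed recovery
  # study runs in the acceptance suite)
  ft <- simulateFeatureTable(syntheticFeatureSpec(nPerClass = 30,
                                                  nInformative = 3,
                                                  nNoise = 7,
                                                  classSeparation = 4,
                                                  seed = 101))
  ev <- fitnessEvaluator(ft, k = 3, seed = 201)
  ctrl <- optimControl(populationSize = 15, maxIterations = 40)
  for (opt in list(psoOptimize, aloOptimize)) {
    res <- opt(ev, control = ctrl, seed = 1, init = rep(1, 10))
    w <- bestWeights(res)
    expect_gt(mean(w[1:3]), mean(w[4:10]))
    expect_gte(bestFitness(res), evaluateFitness(rep(1, 10), ev))
  }
})
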