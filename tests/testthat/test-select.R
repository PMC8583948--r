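# Standardized toy training data with informative and noise features.
toyTrainingData <- function(n = 30, pInf = 3, pNoise = 7, beta = 2,
                            seed = 1) {
  withr::local_seed(seed)
  p <- pInf + pNoise
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("F%02d", seq_len(p))))
  eta <- x[, seq_len(pInf), drop = FALSE] %*% rep(beta, pInf)
  y <- ifelse(runif(n) < plogis(eta), "case", "control")
  # guarantee both classes
  if (length(unique(y)) < 2) y[1:2] <- c("case", "control")
  list(x = scale(x), y = factor(y, levels = c("control", "case")))
}

test_that("the unpenalized fit matches a base-glm IRLS oracle", {
  withr::local_seed(5)
  x <- matrix(rnorm(120 * 2), 120, 2, dimnames = list(NULL, c("F1", "F2")))
  yb <- as.numeric(runif(120) < plogis(0.5 * x[, 1] - 0.8 * x[, 2]))
  fit <- elasticNetFit(x, yb, alpha = 0.5, lambda = 0)
  oracle <- glmLogisticOracle(x, yb)
  expect_equal(fit$intercept, unname(oracle[1]), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients), unname(oracle[-1]),
               tolerance = 1e-4)
})

test_that("full lasso shrinkage leaves only the prevalence intercept", {
  withr::local_seed(6)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("F1", "F2")))
  yb <- rep(c(0, 1), c(8, 12))
  fit <- elasticNetFit(x, yb, alpha = 1, lambda = 50)
  expect_equal(unname(fit$coefficients), c(0, 0))
  expect_equal(fit$intercept, log(12 / 8), tolerance = 1e-6)
})

test_that("lasso sparsity is non-increasing in lambda", {
  d <- toyTrainingData(seed = 7)
  lambdas <- c(0.001, 0.01, 0.05, 0.1, 0.3)
  nz <- vapply(lambdas, function(l)
    sum(elasticNetFit(d$x, d$y, alpha = 1, lambda = l)$coefficients != 0),
    numeric(1))
  expect_true(all(diff(nz) <= 0))
})

test_that("cross-validated elastic net reaches high accuracy on strong signal", {
  d <- toyTrainingData(n = 40, beta = 3, seed = 8)
  model <- fitElasticNet(d$x, d$y, cvConfig(folds = 5, repeats = 2, seed = 1))
  expect_s4_class(model, "ElasticNetModel")
  expect_gte(cvAccuracy(model), 0.9)
  expect_false(model@looUsed)
})

test_that("leave-one-out replaces k-fold on tiny classes and is recorded", {
  d <- toyTrainingData(n = 12, beta = 3, seed = 9)
  model <- fitElasticNet(d$x, d$y, cvConfig(folds = 10, repeats = 5, seed = 1))
  expect_true(model@looUsed)
  # deterministic: same call gives the identical model
  model2 <- fitElasticNet(d$x, d$y, cvConfig(folds = 10, repeats = 5, seed = 1))
  expect_equal(model@coefficients, model2@coefficients)
  expect_equal(model@lambda, model2@lambda)
})

test_that("importance ranking orders by |coefficient| with lexicographic ties", {
  m <- new("ElasticNetModel", alpha = 1, lambda = 0.1, intercept = 0,
           coefficients = c(a = 2, b = -3, c = 0), cvAccuracy = 1,
           looUsed = FALSE)
  r <- rankImportance(m)
  expect_identical(r@featureIds, c("b", "a", "c"))

  z <- new("ElasticNetModel", alpha = 1, lambda = 0.1, intercept = 0,
           coefficients = c(q = 0, b = 0, a = 0), cvAccuracy = 1,
           looUsed = FALSE)
  expect_identical(rankImportance(z)@featureIds, c("a", "b", "q"))

  withr::local_seed(10)
  cf <- setNames(rnorm(8), paste0("F", 1:8))
  mr <- new("ElasticNetModel", alpha = 1, lambda = 0.1, intercept = 0,
            coefficients = cf, cvAccuracy = 1, looUsed = FALSE)
  expect_identical(rankImportance(mr)@featureIds,
                   names(sort(-abs(cf))))
})

test_that("RFE returns exactly s features per size and recovers informative sets", {
  d <- toyTrainingData(n = 40, pInf = 3, pNoise = 20, beta = 3, seed = 11)
  models <- rfe(d$x, d$y, sizes = c(3, 5, 10),
                cv = cvConfig(folds = 5, repeats = 1, seed = 2))
  expect_length(models, 3L)
  for (m in models) {
    expect_s4_class(m, "SelectionModel")
    expect_length(selectedFeatures(m), m@sizeParameter)
  }
  expect_setequal(selectedFeatures(models[[1]]), c("F01", "F02", "F03"))
})

test_that("RFE at the full feature count selects everything, oversizes error", {
  d <- toyTrainingData(n = 20, pInf = 2, pNoise = 2, seed = 12)
  models <- rfe(d$x, d$y, sizes = ncol(d$x),
                cv = cvConfig(folds = 5, repeats = 1, seed = 3))
  expect_setequal(selectedFeatures(models[[1]]), colnames(d$x))
  expect_error(rfe(d$x, d$y, sizes = ncol(d$x) + 1), "sizes")
})

test_that("mRMR penalizes a duplicated feature behind an independent one", {
  withr::local_seed(13)
  n <- 40
  yb <- rep(c(0, 1), each = n / 2)
  x1 <- yb + rnorm(n, 0, 0.4)
  x2 <- x1                      # exact duplicate of x1
  x3 <- yb + rnorm(n, 0, 2.5)   # weak but independent signal
  x <- cbind(x1 = x1, x2 = x2, x3 = x3)
  r <- mrmr(x, ifelse(yb == 1, "case", "control"), 3)
  expect_identical(r@featureIds, c("x1", "x3", "x2"))
})

test_that("mRMR with one pick takes the most correlated feature", {
  withr::local_seed(14)
  yb <- rep(c(0, 1), each = 10)
  x <- cbind(a = rnorm(20), b = yb + rnorm(20, 0, 0.2), c = rnorm(20))
  r <- mrmr(x, ifelse(yb == 1, "case", "control"), 1)
  best <- names(which.max(abs(cor(x, yb))[, 1]))
  expect_identical(r@featureIds, best)
})

test_that("mRMR equals the exhaustive greedy oracle on random fixtures", {
  for (seed in c(15, 16, 17)) {
    withr::local_seed(seed)
    n <- 24; p <- 10
    yb <- rep(c(0, 1), each = n / 2)
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("G%02d", 1:p)))
    x[, 1:3] <- x[, 1:3] + yb
    y <- ifelse(yb == 1, "case", "control")
    r <- mrmr(x, y, 4)
    expect_identical(r@featureIds, naiveMrmr(x, yb, 4))
  }
})

test_that("mRMR ordering is invariant to column permutation", {
  withr::local_seed(18)
  n <- 20; p <- 6
  yb <- rep(c(0, 1), each = n / 2)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, sprintf("H%d", 1:p)))
  x[, 1:2] <- x[, 1:2] + yb
  y <- ifelse(yb == 1, "case", "control")
  ref <- mrmr(x, y, p)@featureIds
  perm <- sample(p)
  expect_identical(mrmr(x[, perm], y, p)@featureIds, ref)
})

test_that("a constant feature is never selected before informative ones", {
  withr::local_seed(19)
  yb <- rep(c(0, 1), each = 10)
  x <- cbind(flat = rep(1, 20), s1 = yb + rnorm(20, 0, 0.3),
             s2 = rnorm(20))
  r <- mrmr(x, ifelse(yb == 1, "case", "control"), 3)
  expect_identical(r@featureIds[1], "s1")
  expect_equal(unname(r@scores["flat"]), 0)
  expect_true(which(r@featureIds == "flat") > 1)
})

test_that("evaluation produces a clean confusion matrix on separated data", {
  d <- toyTrainingData(n = 30, beta = 4, seed = 20)
  model <- fitElasticNet(d$x, d$y, cvConfig(folds = 5, repeats = 1, seed = 4))
  sel <- new("SelectionModel", algorithm = "mrmr", sizeParameter = ncol(d$x),
             selected = colnames(d$x), refit = model,
             cvAccuracy = cvAccuracy(model))
  withr::local_seed(21)
  xt <- matrix(rnorm(10 * ncol(d$x)), 10,
               dimnames = list(NULL, colnames(d$x)))
  xt[, 1:3] <- xt[, 1:3] + 4  # push strongly toward case
  cm <- evaluateSelection(sel, xt, rep("case", 10))
  expect_equal(cm@fn, 0L)
  expect_equal(cm@tp + cm@fp + cm@tn + cm@fn, 10L)
})

test_that("evaluation guards empty tests and missing features; ties go to case", {
  m <- new("ElasticNetModel", alpha = 1, lambda = 1, intercept = 0,
           coefficients = c(F1 = 0), cvAccuracy = 0.5, looUsed = TRUE)
  x <- matrix(0, 4, 1, dimnames = list(NULL, "F1"))
  expect_error(evaluateSelection(m, x[0, , drop = FALSE], character(0)),
               "empty test")
  expect_error(evaluateSelection(m, matrix(0, 2, 1,
                                           dimnames = list(NULL, "other")),
                                 c("case", "control")), "missing")
  # intercept-only model, balanced labels: probability exactly 0.5 -> case
  cm <- evaluateSelection(m, x, c("case", "case", "control", "control"))
  expect_equal(accuracy(cm), 0.5)
  expect_equal(cm@tn, 0L)
})
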