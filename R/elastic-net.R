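#' Cross-validation settings
#'
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats (default 5).
#' @param seed Seed for fold assignment.
#' @return A [CVConfig-class].
#' @details When the smaller class has fewer members than `folds`, k-fold
#'   cross-validation is not feasible as specified; the fitting routines
#'   then substitute leave-one-out (which is deterministic, so repeats
#'   collapse to one) and record the substitution in the fitted model.
#' @export
cvConfig <- function(folds = 10L, repeats = 5L, seed = 1L) {
  new("CVConfig", folds = as.integer(folds), repeats = as.integer(repeats),
      seed = as.integer(seed))
}

# labels -> 0/1 with case = 1 (0/1 numerics pass through)
labelBinary <- function(y) {
  if (is.numeric(y) && all(y %in% c(0, 1))) return(as.numeric(y))
  y <- factor(as.character(y), levels = c("control", "case"))
  if (anyNA(y)) stop("labels must be 'control' or 'case'")
  as.numeric(y == "case")
}

# glmnet refuses single-column predictor matrices; pad with an all-zero
# column that can never acquire a nonzero coefficient
padMatrix <- function(x) {
  if (ncol(x) >= 2L) return(x)
  cbind(x, `.pad.` = 0)
}

dropPad <- function(beta) beta[names(beta) != ".pad."]

# glmnet warns on every fit with < 8 observations per class; that is the
# operating regime of this package (by design, tiny cohorts), so the
# warning is muffled rather than surfaced hundreds of times per run
quietGlmnet <- function(...) {
  withCallingHandlers(glmnet::glmnet(...),
    warning = function(w) {
      if (grepl("fewer than 8", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Penalized logistic fit at fixed hyperparameters
#'
#' Minimises the penalized logistic deviance
#' `mean negative log-likelihood + lambda * (alpha * sum|b| +
#' (1 - alpha)/2 * sum b^2)` via coordinate descent (glmnet), warm-started
#' along a decreasing lambda path for numerical stability. Predictors are
#' used as given (no internal re-standardization): the pipeline supplies
#' standardized features, which keeps coefficients comparable.
#'
#' @param x Numeric samples x features matrix.
#' @param y Labels (`control`/`case`), or a 0/1 vector with case = 1.
#' @param alpha Mixing parameter in `[0, 1]`.
#' @param lambda Penalty strength >= 0 (0 gives the unpenalized fit).
#' @return List with `intercept` and named `coefficients`.
#' @export
elasticNetFit <- function(x, y, alpha, lambda) {
  yb <- if (is.numeric(y) && all(y %in% c(0, 1))) y else labelBinary(y)
  if (length(unique(yb)) < 2L)
    stop("elasticNetFit: training data contain a single class")
  xp <- padMatrix(as.matrix(x))
  n <- nrow(xp)
  lmax <- max(max(abs(crossprod(xp, yb - mean(yb)))) / n / max(alpha, 1e-3),
              lambda, 1e-4)
  path <- sort(unique(c(exp(seq(log(lmax * 1.0001), log(max(lambda, lmax * 1e-4)),
                                length.out = 25L)), lambda)),
               decreasing = TRUE)
  fit <- quietGlmnet(xp, yb, family = "binomial", alpha = alpha,
                        lambda = path, standardize = FALSE, thresh = 1e-12,
                        maxit = 1e6)
  # the target lambda is a member of the fitted path: read its column
  # directly rather than interpolating across the path
  idx <- which(abs(fit$lambda - lambda) < 1e-12 * max(1, lambda))[1]
  cf <- if (!is.na(idx)) c(fit$a0[[idx]], as.numeric(fit$beta[, idx]))
        else as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(xp))
  list(intercept = cf[[1]], coefficients = dropPad(cf[-1]))
}

# Linear predictor -> P(case)
predictProb <- function(intercept, coefficients, x) {
  feats <- names(coefficients)
  if (!all(feats %in% colnames(x)))
    stop("prediction: features missing from the supplied table")
  as.numeric(stats::plogis(
    intercept + as.matrix(x[, feats, drop = FALSE]) %*% coefficients))
}

# Stratified fold assignment (list of held-out index vectors per repeat)
makeFolds <- function(yb, folds, repeats, seed) {
  n <- length(yb)
  withSeed(seed, {
    lapply(seq_len(repeats), function(r) {
      assign <- integer(n)
      for (cl in unique(yb)) {
        idx <- sample(which(yb == cl))
        assign[idx] <- rep_len(seq_len(folds), length(idx))
      }
      lapply(seq_len(folds), function(f) which(assign == f))
    })
  })
}

#' Elastic-net logistic regression with repeated cross-validation
#'
#' Fits penalized logistic regression over a grid of mixing parameters
#' `alpha` and penalty strengths `lambda`, choosing the pair that maximises
#' mean cross-validated accuracy (prediction threshold 0.5), then refits on
#' the full training set at the chosen pair. With fewer samples in a class
#' than folds, leave-one-out is substituted for k-fold (see [cvConfig()]).
#' Accuracy ties are resolved toward the sparser model (larger lambda,
#' then larger alpha).
#'
#' @param x Numeric samples x features matrix (standardized).
#' @param y Labels (`control`/`case`).
#' @param cv A [CVConfig-class].
#' @param alphaGrid Numeric vector of mixing parameters.
#' @param lambdaGrid Numeric vector of penalties; by default 20 values
#'   log-spaced over `[1e-4, 10] * lambda_max`, with `lambda_max` the
#'   smallest penalty that zeroes all lasso coefficients on this data.
#' @return An [ElasticNetModel-class].
#' @export
fitElasticNet <- function(x, y, cv = cvConfig(),
                          alphaGrid = seq(0.1, 1, by = 0.1),
                          lambdaGrid = NULL) {
  x <- as.matrix(x)
  yb <- labelBinary(y)
  if (length(unique(yb)) < 2L)
    stop("fitElasticNet: training data contain a single class")
  n <- nrow(x)

  if (is.null(lambdaGrid)) {
    lmax <- max(abs(crossprod(padMatrix(x), yb - mean(yb)))) / n
    lambdaGrid <- lmax * 10^seq(-4, 1, length.out = 20L)
  }
  lambdaGrid <- sort(lambdaGrid, decreasing = TRUE)

  loo <- min(table(yb)) < cv@folds
  if (loo) {
    foldSets <- list(as.list(seq_len(n)))
  } else {
    foldSets <- makeFolds(yb, cv@folds, cv@repeats, cv@seed)
  }

  correct <- array(0, dim = c(length(alphaGrid), length(lambdaGrid)))
  total <- 0L
  xp <- padMatrix(x)
  for (rep in foldSets) {
    for (held in rep) {
      if (!length(held)) next
      ytr <- yb[-held]
      if (length(unique(ytr)) < 2L) next
      total <- total + length(held)
      for (a in seq_along(alphaGrid)) {
        fit <- quietGlmnet(xp[-held, , drop = FALSE], ytr,
                              family = "binomial", alpha = alphaGrid[a],
                              lambda = lambdaGrid, standardize = FALSE,
                              thresh = 1e-9, maxit = 1e6)
        prob <- stats::predict(fit, xp[held, , drop = FALSE],
                               s = lambdaGrid, type = "response")
        pred <- prob >= 0.5
        correct[a, ] <- correct[a, ] +
          colSums(pred == matrix(yb[held] == 1, length(held),
                                 length(lambdaGrid)))
      }
    }
  }
  acc <- correct / total

  best <- which(acc == max(acc), arr.ind = TRUE)
  # sparser first: largest lambda, then largest alpha
  best <- best[order(best[, 2], -best[, 1]), , drop = FALSE]
  aIdx <- best[1, 1]
  lIdx <- best[1, 2]

  refit <- elasticNetFit(x, yb, alphaGrid[aIdx], lambdaGrid[lIdx])
  new("ElasticNetModel",
      alpha = alphaGrid[aIdx], lambda = lambdaGrid[lIdx],
      intercept = refit$intercept, coefficients = refit$coefficients,
      cvAccuracy = max(acc), looUsed = loo)
}

#' Rank features by elastic-net importance
#'
#' Scores each feature by the absolute value of its coefficient (inputs
#' are standardized, so magnitudes are comparable); ties are broken
#' lexicographically by feature id.
#'
#' @param model An [ElasticNetModel-class].
#' @return A [RankedFeatures-class] with algorithm `"enet_importance"`.
#' @export
rankImportance <- function(model) {
  stopifnot(is(model, "ElasticNetModel"))
  sc <- abs(model@coefficients)
  ord <- order(-sc, names(sc))
  new("RankedFeatures", algorithm = "enet_importance",
      featureIds = names(sc)[ord], scores = sc[ord])
}
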