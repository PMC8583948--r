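# Dual-route feature selection over elastic-net logistic regression:
# recursive feature elimination under outer resampling, and mRMR greedy
# ranking with a correlation-based mutual-information surrogate.

#' Recursive feature elimination
#'
#' Wrapper selection under outer resampling (same fold policy as
#' [fitElasticNet()]; leave-one-out when a class is smaller than the fold
#' count). Within each resample an elastic net is fit on all features and
#' features are ranked by importance once; for each candidate subset size
#' the top-ranked subset is refit at the resample's chosen hyperparameters
#' and scored on the held-out samples. Each candidate size yields one
#' [SelectionModel-class] whose selected set is the top of the
#' full-training-set ranking and whose `refit` is a fully re-tuned elastic
#' net on that subset; the `"bestSize"` attribute of the returned list is
#' the accuracy argmax (ties toward the smaller size).
#'
#' @param x Numeric samples x features matrix (standardized).
#' @param y Labels (`control`/`case`).
#' @param sizes Integer vector of candidate subset sizes (each
#'   `<= ncol(x)`).
#' @param cv A [CVConfig-class] for the outer resampling (also reused,
#'   reseeded per resample, for the inner hyperparameter search).
#' @return List of [SelectionModel-class], one per candidate size, with
#'   attribute `"bestSize"`.
#' @export
rfe <- function(x, y, sizes, cv = cvConfig()) {
  x <- as.matrix(x)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 1L) || any(sizes > ncol(x)))
    stop("rfe: candidate sizes must lie in [1, #features]")
  yb <- labelBinary(y)
  n <- nrow(x)

  loo <- min(table(yb)) < cv@folds
  foldSets <- if (loo) list(as.list(seq_len(n)))
              else makeFolds(yb, cv@folds, cv@repeats, cv@seed)

  correct <- stats::setNames(numeric(length(sizes)), sizes)
  total <- 0L
  resample <- 0L
  for (rep in foldSets) {
    for (held in rep) {
      if (!length(held)) next
      ytr <- yb[-held]
      if (length(unique(ytr)) < 2L) next
      resample <- resample + 1L
      total <- total + length(held)
      innerCv <- cvConfig(cv@folds, cv@repeats,
                          cv@seed + 7919L * resample)
      fit <- fitElasticNet(x[-held, , drop = FALSE], ytr, innerCv)
      ranking <- rankImportance(fit)@featureIds
      for (i in seq_along(sizes)) {
        keep <- ranking[seq_len(sizes[i])]
        sub <- elasticNetFit(x[-held, keep, drop = FALSE], ytr,
                             fit@alpha, fit@lambda)
        prob <- predictProb(sub$intercept, sub$coefficients,
                            x[held, , drop = FALSE])
        correct[i] <- correct[i] + sum((prob >= 0.5) == (yb[held] == 1))
      }
    }
  }
  meanAcc <- correct / total

  fullFit <- fitElasticNet(x, yb2factor(yb), cv)
  ranking <- rankImportance(fullFit)@featureIds
  models <- lapply(seq_along(sizes), function(i) {
    selected <- ranking[seq_len(sizes[i])]
    refit <- fitElasticNet(x[, selected, drop = FALSE], yb2factor(yb), cv)
    new("SelectionModel", algorithm = "rfe", sizeParameter = sizes[i],
        selected = selected, refit = refit, cvAccuracy = meanAcc[[i]])
  })
  attr(models, "bestSize") <- sizes[which.max(meanAcc)]
  models
}

yb2factor <- function(yb) {
  factor(ifelse(yb == 1, "case", "control"), levels = c("control", "case"))
}

# correlation-based mutual-information surrogate: -1/2 ln(1 - rho^2),
# with rho clamped away from +-1; constants carry zero information
miSurrogate <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  rho <- stats::cor(a, b)
  rho <- max(min(rho, 1 - 1e-12), -(1 - 1e-12))
  -0.5 * log(1 - rho^2)
}

#' Minimal-redundancy-maximal-relevance ranking
#'
#' Greedy forward selection with the MID (difference) scheme: relevance of
#' a feature is the Gaussian mutual-information surrogate
#' `-1/2 ln(1 - rho^2)` of its point-biserial correlation with the binary
#' label; redundancy is the mean surrogate over the features already
#' selected; each step picks the feature maximising relevance minus
#' redundancy (the first pick maximises relevance alone). Ties are broken
#' lexicographically by feature id; constant features have zero relevance
#' and are never picked before an informative one.
#'
#' @param x Numeric samples x features matrix (standardized).
#' @param y Labels (`control`/`case`).
#' @param nSelect Number of features to rank (`<= ncol(x)`).
#' @return A [RankedFeatures-class] with algorithm `"mrmr"`; scores are
#'   the step criteria at selection time.
#' @export
mrmr <- function(x, y, nSelect) {
  x <- as.matrix(x)
  nSelect <- as.integer(nSelect)
  if (nSelect < 1L || nSelect > ncol(x))
    stop("mrmr: nSelect must lie in [1, #features]")
  yb <- labelBinary(y)
  feats <- colnames(x)

  relevance <- vapply(feats, function(f) miSurrogate(x[, f], yb), numeric(1))
  selected <- character(0)
  scores <- numeric(0)
  candidates <- feats
  # cache pairwise surrogates against selected features as they accrue
  redSum <- stats::setNames(numeric(length(feats)), feats)

  for (step in seq_len(nSelect)) {
    crit <- if (length(selected) == 0L) relevance[candidates]
            else relevance[candidates] - redSum[candidates] / length(selected)
    ord <- order(-crit, candidates)
    pick <- candidates[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, crit[[ord[1]]])
    candidates <- setdiff(candidates, pick)
    if (length(candidates))
      redSum[candidates] <- redSum[candidates] +
        vapply(candidates, function(f) miSurrogate(x[, f], x[, pick]),
               numeric(1))
  }
  names(scores) <- selected
  new("RankedFeatures", algorithm = "mrmr", featureIds = selected,
      scores = scores)
}

#' Build a SelectionModel from an mRMR ranking
#'
#' Truncates an mRMR run at its top `nSelect` features and refits an
#' elastic net restricted to them, mirroring the RFE route so both can
#' feed the consensus rule.
#'
#' @inheritParams mrmr
#' @param cv A [CVConfig-class] for the refit.
#' @return A [SelectionModel-class] with algorithm `"mrmr"`.
#' @export
mrmrSelection <- function(x, y, nSelect, cv = cvConfig()) {
  ranking <- mrmr(x, y, nSelect)
  selected <- ranking@featureIds
  refit <- fitElasticNet(as.matrix(x)[, selected, drop = FALSE], y, cv)
  new("SelectionModel", algorithm = "mrmr",
      sizeParameter = as.integer(nSelect), selected = selected,
      refit = refit, cvAccuracy = refit@cvAccuracy)
}

makeConfusion <- function(truthCase, predCase) {
  tp <- sum(truthCase & predCase)
  fp <- sum(!truthCase & predCase)
  tn <- sum(!truthCase & !predCase)
  fn <- sum(truthCase & !predCase)
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      tn = as.integer(tn), fn = as.integer(fn),
      accuracy = (tp + tn) / max(tp + fp + tn + fn, 1L))
}

#' Evaluate a model on held-out samples
#'
#' Predicts class probabilities on the test table with the (re)fitted
#' elastic net and thresholds at 0.5 (probability of `case` at or above
#' 0.5 predicts `case`, so an intercept-only model on balanced data
#' scores accuracy 0.5). Case is the positive class.
#'
#' @param model A [SelectionModel-class] (its `refit` is used) or an
#'   [ElasticNetModel-class].
#' @param test Numeric samples x features matrix containing at least the
#'   model's features (preprocessed with the training parameters).
#' @param labels Labels (`control`/`case`) for the test samples.
#' @return A [ConfusionMatrix-class].
#' @export
evaluateSelection <- function(model, test, labels) {
  enet <- if (is(model, "SelectionModel")) model@refit else model
  stopifnot(is(enet, "ElasticNetModel"))
  test <- as.matrix(test)
  if (nrow(test) == 0L)
    stop("evaluateSelection: empty test set")
  if (!all(names(enet@coefficients) %in% colnames(test)))
    stop("evaluateSelection: selected features missing from the test table")
  yb <- labelBinary(labels)
  prob <- predictProb(enet@intercept, enet@coefficients, test)
  makeConfusion(yb == 1, prob >= 0.5)
}
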