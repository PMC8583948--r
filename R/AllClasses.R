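#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' OmicsLayer: one quantified omics layer
#'
#' An `OmicsLayer` holds a single feature-by-sample intensity matrix
#' (e.g. TMT reporter-ion relative abundances for proteins, or LC-MS peak
#' intensities for metabolites) together with a two-level group label per
#' sample.  It extends [SummarizedExperiment::SummarizedExperiment] with a
#' layer tag; the single assay is named `"intensity"`, missing measurements
#' are `NA`, and `colData(x)$group` is a factor with levels
#' `c("control", "case")`.
#'
#' @slot layer Character scalar, `"protein"` or `"metabolite"`.
#'
#' @seealso [OmicsLayer()] for construction, [runDifferential()] for the
#'   per-layer screen.
#' @export
setClass("OmicsLayer",
  contains = "SummarizedExperiment",
  slots = c(layer = "character")
)

setValidity("OmicsLayer", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% c("protein", "metabolite"))
    msg <- c(msg, "'layer' must be \"protein\" or \"metabolite\"")
  if (!"group" %in% colnames(colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- colData(object)$group
    if (!is.factor(g) || !identical(levels(g), c("control", "case")))
      msg <- c(msg, "'group' must be a factor with levels control, case")
    if (anyNA(g))
      msg <- c(msg, "every sample must have a group")
  }
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    v <- assay(object, "intensity")
    if (any(v < 0, na.rm = TRUE))
      msg <- c(msg, "intensities must be non-negative")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "feature ids must be unique and non-NULL")
  }
  if (length(msg)) msg else TRUE
})

#' IntegratedDataset: merged significant features, split and preprocessing
#'
#' Container for the integration step: the merged sample-by-feature table
#' restricted to significant features of both layers, its stratified
#' train/test partition, the per-feature scaling parameters learned on the
#' training samples, and the K used for nearest-neighbour imputation.
#' Rows of `trainValues`/`testValues` are samples, columns are features
#' tagged by their layer of origin in `featureLayer`.
#'
#' @slot trainValues,testValues Numeric matrices (samples x features) after
#'   log transform (metabolites), scaling and imputation.
#' @slot trainIds,testIds Character vectors; disjoint, union = all samples.
#' @slot labels Named factor (levels control, case) over all samples.
#' @slot featureLayer Named character vector mapping feature id ->
#'   `"protein"`/`"metabolite"`.
#' @slot scaling `data.frame` with columns `feature`, `mean`, `sd`,
#'   `constant`; one row per feature, estimated on training data only.
#' @slot imputationK Integer, neighbours used by [knnImpute()].
#' @slot seed Integer seed that fixed the train/test split.
#' @export
setClass("IntegratedDataset",
  slots = c(
    trainValues = "matrix", testValues = "matrix",
    trainIds = "character", testIds = "character",
    labels = "factor", featureLayer = "character",
    scaling = "data.frame", imputationK = "integer",
    seed = "integer"
  )
)

setValidity("IntegratedDataset", function(object) {
  msg <- character()
  if (length(intersect(object@trainIds, object@testIds)))
    msg <- c(msg, "train and test ids must be disjoint")
  if (!setequal(c(object@trainIds, object@testIds), names(object@labels)))
    msg <- c(msg, "train/test ids must partition the labelled samples")
  feats <- colnames(object@trainValues)
  if (!identical(feats, colnames(object@testValues)) && ncol(object@testValues) > 0)
    msg <- c(msg, "train and test tables must share feature columns")
  if (!setequal(feats, object@scaling$feature))
    msg <- c(msg, "scaling must have one entry per feature")
  if (!setequal(feats, names(object@featureLayer)))
    msg <- c(msg, "featureLayer must tag every feature")
  if (length(msg)) msg else TRUE
})

#' CVConfig: repeated k-fold cross-validation settings
#'
#' @slot folds Integer >= 2; reduced to leave-one-out when a class has
#'   fewer members than `folds`.
#' @slot repeats Integer >= 1 (collapsed to 1 under leave-one-out, which is
#'   deterministic).
#' @slot seed Integer seed for fold assignment.
#' @export
setClass("CVConfig",
  slots = c(folds = "integer", repeats = "integer", seed = "integer"))

setValidity("CVConfig", function(object) {
  if (object@folds < 2L) return("'folds' must be >= 2")
  if (object@repeats < 1L) return("'repeats' must be >= 1")
  TRUE
})

#' ElasticNetModel: penalized logistic regression fit
#'
#' Result of [fitElasticNet()]: the mixing parameter alpha, penalty lambda
#' (chosen to maximize mean cross-validated accuracy), the refit intercept
#' and coefficients on the full training set, and the achieved CV accuracy.
#'
#' @slot alpha Mixing parameter in `[0, 1]` (1 = lasso, 0 = ridge).
#' @slot lambda Penalty strength >= 0.
#' @slot intercept Numeric scalar.
#' @slot coefficients Named numeric vector, one entry per fitted feature.
#' @slot cvAccuracy Mean cross-validated accuracy at the chosen (alpha, lambda).
#' @slot looUsed Logical; `TRUE` when folds exceeded a class count and
#'   leave-one-out was substituted.
#' @export
setClass("ElasticNetModel",
  slots = c(alpha = "numeric", lambda = "numeric", intercept = "numeric",
            coefficients = "numeric", cvAccuracy = "numeric",
            looUsed = "logical"))

setValidity("ElasticNetModel", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must be in [0,1]")
  if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
  if (is.null(names(object@coefficients)) && length(object@coefficients))
    msg <- c(msg, "coefficients must be named by feature")
  if (length(msg)) msg else TRUE
})

#' RankedFeatures: an importance-ordered feature list
#'
#' @slot algorithm `"enet_importance"` or `"mrmr"`.
#' @slot featureIds Character vector in rank order (best first).
#' @slot scores Named numeric vector aligned with `featureIds`
#'   (non-increasing for `enet_importance`; mRMR scores are the greedy
#'   step criteria, non-increasing only within the relevance-first pick).
#' @export
setClass("RankedFeatures",
  slots = c(algorithm = "character", featureIds = "character",
            scores = "numeric"))

setValidity("RankedFeatures", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("enet_importance", "mrmr"))
    msg <- c(msg, "algorithm must be 'enet_importance' or 'mrmr'")
  if (anyDuplicated(object@featureIds))
    msg <- c(msg, "feature ids must be unique")
  if (!identical(names(object@scores), object@featureIds))
    msg <- c(msg, "scores must be named by featureIds in the same order")
  if (length(msg)) msg else TRUE
})

#' SelectionModel: a fitted feature-selection route
#'
#' One selector outcome: the algorithm (RFE at a candidate subset size, or
#' mRMR truncated at a top-k), the selected feature set, the elastic-net
#' model refit on those features, and its cross-validated accuracy.
#'
#' @slot algorithm `"rfe"` or `"mrmr"`.
#' @slot sizeParameter Integer: subset size (RFE) or top-k (mRMR).
#' @slot selected Character vector of selected feature ids.
#' @slot refit [ElasticNetModel-class] restricted to `selected`.
#' @slot cvAccuracy Resampled accuracy associated with this size.
#' @export
setClass("SelectionModel",
  slots = c(algorithm = "character", sizeParameter = "integer",
            selected = "character", refit = "ElasticNetModel",
            cvAccuracy = "numeric"))

setValidity("SelectionModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("rfe", "mrmr"))
    msg <- c(msg, "algorithm must be 'rfe' or 'mrmr'")
  if (length(object@selected) != object@sizeParameter)
    msg <- c(msg, "selected set size must equal sizeParameter")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: 2x2 held-out classification outcome
#'
#' Case (`"case"`, i.e. diseased) is the positive class.
#'
#' @slot tp,fp,tn,fn Non-negative integer counts.
#' @slot accuracy `(tp + tn) / (tp + fp + tn + fn)`.
#' @export
setClass("ConfusionMatrix",
  slots = c(tp = "integer", fp = "integer", tn = "integer", fn = "integer",
            accuracy = "numeric"))

setValidity("ConfusionMatrix", function(object) {
  n <- object@tp + object@fp + object@tn + object@fn
  if (any(c(object@tp, object@fp, object@tn, object@fn) < 0L))
    return("counts must be non-negative")
  if (n > 0L && abs(object@accuracy - (object@tp + object@tn) / n) > 1e-12)
    return("accuracy must equal (tp + tn)/n")
  TRUE
})

#' ConsensusResult: end-to-end pipeline outcome
#'
#' Returned by [runPipeline()]: the per-layer differential tables, the
#' integrated dataset, the individual selection models, the consensus
#' feature panel (features selected by at least `minOccurrence` of the
#' source models), the final elastic-net classifier restricted to that
#' panel, and its confusion matrix on the held-out test samples.
#'
#' @slot proteinStats,metaboliteStats [S4Vectors::DataFrame] of per-feature
#'   differential results (see [runDifferential()]).
#' @slot dataset [IntegratedDataset-class].
#' @slot sourceModels List of [SelectionModel-class].
#' @slot minOccurrence Integer occurrence threshold of the consensus rule.
#' @slot consensusFeatures Character vector (lexicographic order).
#' @slot finalModel [ElasticNetModel-class] fit on the consensus features.
#' @slot testConfusion [ConfusionMatrix-class] on the test partition.
#' @slot provenance List of seeds and stage parameters used.
#' @export
setClass("ConsensusResult",
  slots = c(proteinStats = "DataFrame", metaboliteStats = "DataFrame",
            dataset = "IntegratedDataset", sourceModels = "list",
            minOccurrence = "integer", consensusFeatures = "character",
            finalModel = "ElasticNetModel", testConfusion = "ConfusionMatrix",
            provenance = "list"))

setValidity("ConsensusResult", function(object) {
  pool <- unique(unlist(lapply(object@sourceModels, selectedFeatures)))
  if (!all(object@consensusFeatures %in% pool))
    return("consensus features must come from the source selections")
  TRUE
})
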