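#' Consensus features across selection models
#'
#' Features selected by at least `minOccurrence` of the supplied selection
#' sets (the study configuration — two RFE subset sizes plus one mRMR
#' top-k with `minOccurrence = 2` — is one instantiation of this rule).
#' `minOccurrence = 1` gives the union, `minOccurrence = length(sets)` the
#' intersection. The result is sorted lexicographically for deterministic
#' serialization.
#'
#' @param selections List of character vectors (feature-id sets), or a
#'   list of [SelectionModel-class] objects.
#' @param minOccurrence Integer in `[1, length(selections)]`.
#' @return Character vector of consensus feature ids.
#' @examples
#' consensusFeatures(list(c("A", "B", "C"), c("A", "B", "D"), c("A", "E")))
#' @export
consensusFeatures <- function(selections, minOccurrence = 2L) {
  if (length(selections) < 1L)
    stop("consensusFeatures: at least one selection set is required")
  sets <- lapply(selections, function(s)
    if (is(s, "SelectionModel")) selectedFeatures(s) else as.character(s))
  minOccurrence <- as.integer(minOccurrence)
  if (minOccurrence < 1L || minOccurrence > length(sets))
    stop("consensusFeatures: minOccurrence must lie in [1, #sets]")
  counts <- table(unlist(lapply(sets, unique)))
  sort(names(counts)[counts >= minOccurrence])
}

#' Fit the final consensus classifier
#'
#' Elastic-net logistic regression restricted to the consensus features,
#' with the same cross-validation protocol (and fresh hyperparameter
#' tuning) as [fitElasticNet()].
#'
#' @param x Training samples x features matrix.
#' @param y Labels (`control`/`case`).
#' @param consensus Non-empty character vector of feature ids.
#' @param cv A [CVConfig-class].
#' @return An [ElasticNetModel-class].
#' @export
fitFinal <- function(x, y, consensus, cv = cvConfig()) {
  if (length(consensus) == 0L)
    stop("fitFinal: empty consensus; lower minOccurrence or revisit the ",
         "selection sizes")
  x <- as.matrix(x)
  if (!all(consensus %in% colnames(x)))
    stop("fitFinal: consensus features missing from the training table")
  fitElasticNet(x[, consensus, drop = FALSE], y, cv)
}

#' Pipeline configuration
#'
#' Stage parameters for [runPipeline()], defaulting to the study design:
#' 50% missingness filter, Dixon removal at 0.05, BH significance at
#' adjusted p < 0.05 per layer, 70:30 stratified split, K = 5 imputation,
#' RFE candidate sizes 7 and 9, mRMR top 30, and the 2-of-3 consensus
#' rule. Candidate sizes exceeding the number of integrated features are
#' clamped at run time (small cohorts can yield fewer significant
#' features than the nominal subset sizes).
#'
#' @param maxMissing,alphaOutlier,fdr Differential-screen thresholds.
#' @param ratio,k Integration parameters (split ratio, imputation K).
#' @param rfeSizes Integer vector of RFE candidate subset sizes.
#' @param mrmrTop Integer vector of mRMR top-k values whose selections
#'   enter the consensus (the study used only the best-performing top-30).
#' @param minOccurrence Consensus occurrence threshold.
#' @param folds,repeats Cross-validation settings.
#' @param seed Master seed; split deterministically into stage substreams.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(maxMissing = 0.5, alphaOutlier = 0.05,
                           fdr = 0.05, ratio = 0.7, k = 5L,
                           rfeSizes = c(7L, 9L), mrmrTop = 30L,
                           minOccurrence = 2L, folds = 10L, repeats = 5L,
                           seed = 1L) {
  cfg <- list(maxMissing = maxMissing, alphaOutlier = alphaOutlier,
              fdr = fdr, ratio = ratio, k = as.integer(k),
              rfeSizes = as.integer(rfeSizes), mrmrTop = as.integer(mrmrTop),
              minOccurrence = as.integer(minOccurrence),
              folds = as.integer(folds), repeats = as.integer(repeats),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full integration pipeline
#'
#' End to end: per-layer differential screen ([runDifferential()]),
#' integration of significant features with stratified 70:30 split,
#' training-set scaling and KNN imputation ([integrateLayers()]), RFE and
#' mRMR selection routes ([rfe()], [mrmrSelection()]), the
#' `minOccurrence`-of-N consensus rule ([consensusFeatures()]), the final
#' elastic-net classifier on the consensus panel ([fitFinal()]) and its
#' held-out confusion matrix ([evaluateSelection()]). All stage seeds
#' derive deterministically from `config$seed`, so a rerun with the same
#' inputs and seed reproduces the result bit for bit.
#'
#' @param prot,met [OmicsLayer-class] objects (protein, metabolite).
#' @param config A [pipelineConfig()].
#' @param proteinGeneMap Optional named character vector (feature id ->
#'   gene) used to collapse significant proteins to unique genes before
#'   integration, keeping the smallest adjusted p per gene.
#' @return A [ConsensusResult-class].
#' @export
runPipeline <- function(prot, met, config = pipelineConfig(),
                        proteinGeneMap = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  seeds <- deriveSeeds(config$seed, 4L)

  protStats <- runDifferential(prot, config$maxMissing, config$alphaOutlier,
                               config$fdr)
  if (!is.null(proteinGeneMap))
    protStats <- collapseByGene(protStats, proteinGeneMap)
  metStats <- runDifferential(met, config$maxMissing, config$alphaOutlier,
                              config$fdr)

  dataset <- integrateLayers(protStats, metStats, prot, met,
                             ratio = config$ratio, k = config$k,
                             seed = seeds[1])
  xtr <- dataset@trainValues
  ytr <- dataset@labels[dataset@trainIds]
  p <- ncol(xtr)
  if (p == 0L)
    stop("runPipeline: no significant features to integrate")

  rfeSizes <- sort(unique(pmin(config$rfeSizes, p)))
  mrmrTop <- sort(unique(pmin(config$mrmrTop, p)))

  rfeModels <- rfe(xtr, ytr, rfeSizes, cvConfig(config$folds,
                                                config$repeats, seeds[2]))
  mrmrModels <- lapply(mrmrTop, function(kTop)
    mrmrSelection(xtr, ytr, kTop, cvConfig(config$folds, config$repeats,
                                           seeds[3])))
  sourceModels <- c(rfeModels, mrmrModels)

  consensus <- consensusFeatures(sourceModels,
                                 min(config$minOccurrence,
                                     length(sourceModels)))
  if (length(consensus) == 0L) {
    warning("runPipeline: empty consensus; falling back to the union of ",
            "selections")
    consensus <- consensusFeatures(sourceModels, 1L)
  }
  finalModel <- fitFinal(xtr, ytr, consensus,
                         cvConfig(config$folds, config$repeats, seeds[4]))
  testConfusion <- evaluateSelection(
    finalModel, dataset@testValues, dataset@labels[dataset@testIds])

  new("ConsensusResult",
      proteinStats = protStats, metaboliteStats = metStats,
      dataset = dataset, sourceModels = sourceModels,
      minOccurrence = as.integer(min(config$minOccurrence,
                                     length(sourceModels))),
      consensusFeatures = consensus, finalModel = finalModel,
      testConfusion = testConfusion,
      provenance = list(config = unclass(config),
                        stageSeeds = as.integer(seeds)))
}

modelToList <- function(m) {
  list(alpha = m@alpha, lambda = m@lambda, intercept = m@intercept,
       coefficients = as.list(m@coefficients),
       cvAccuracy = m@cvAccuracy, looUsed = m@looUsed)
}

#' Serialize a ConsensusResult
#'
#' `resultToList()` converts a [ConsensusResult-class] into plain lists
#' (used for JSON output and reproducibility comparison);
#' `writeResults()` writes a results directory: per-layer stats TSVs,
#' one JSON per selection model, the consensus JSON (panel, final model,
#' confusion matrix) and a provenance JSON with all seeds.
#'
#' @param result A [ConsensusResult-class].
#' @return `resultToList()`: a nested list. `writeResults()`: invisibly,
#'   the output directory.
#' @export
resultToList <- function(result) {
  cm <- result@testConfusion
  list(
    consensusFeatures = result@consensusFeatures,
    minOccurrence = result@minOccurrence,
    sourceModels = lapply(result@sourceModels, function(m)
      list(algorithm = m@algorithm, sizeParameter = m@sizeParameter,
           selected = m@selected, cvAccuracy = m@cvAccuracy,
           refit = modelToList(m@refit))),
    finalModel = modelToList(result@finalModel),
    testConfusion = list(tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn,
                         accuracy = cm@accuracy),
    split = list(train = result@dataset@trainIds,
                 test = result@dataset@testIds),
    provenance = result@provenance)
}

#' @param dir Output directory (created if absent).
#' @rdname resultToList
#' @export
writeResults <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeFeatureStats(result@proteinStats, file.path(dir, "protein_stats.tsv"))
  writeFeatureStats(result@metaboliteStats,
                    file.path(dir, "metabolite_stats.tsv"))
  lst <- resultToList(result)
  for (i in seq_along(lst$sourceModels))
    jsonlite::write_json(lst$sourceModels[[i]],
                         file.path(dir, sprintf("model_%s_%d.json",
                                                lst$sourceModels[[i]]$algorithm,
                                                lst$sourceModels[[i]]$sizeParameter)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(lst[c("consensusFeatures", "minOccurrence",
                             "finalModel", "testConfusion")],
                       file.path(dir, "consensus.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cm <- lst$testConfusion
  writeTSV(data.frame(tp = cm$tp, fp = cm$fp, tn = cm$tn, fn = cm$fn,
                      accuracy = cm$accuracy),
           file.path(dir, "confusion_matrix.tsv"))
  jsonlite::write_json(lst[c("split", "provenance")],
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
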