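#' Merge significant features of both layers
#'
#' Restricts both layers to the samples they share, keeps the significant
#' features of each differential table, and binds them into one sample-by-
#' feature matrix. Metabolite intensities are natural-log transformed
#' (zeros become missing); protein abundances are taken as-is (the base of
#' the log only shifts scale and is neutralised by the subsequent
#' per-feature standardization).
#'
#' @param protStats,metStats Differential tables from [runDifferential()].
#' @param prot,met The corresponding [OmicsLayer-class] objects.
#' @return A list with `values` (samples x features matrix), `labels`
#'   (named factor) and `featureLayer` (named character tagging each
#'   feature's layer of origin).
#' @export
mergeLayers <- function(protStats, metStats, prot, met) {
  shared <- intersect(colnames(prot), colnames(met))
  if (length(shared) == 0L)
    stop("mergeLayers: the two layers share no samples")
  gp <- sampleGroups(prot)[shared]
  gm <- sampleGroups(met)[shared]
  if (!identical(as.character(gp), as.character(gm)))
    stop("mergeLayers: group labels disagree between layers on shared samples")

  sigProt <- protStats$feature_id[protStats$significant]
  sigMet <- metStats$feature_id[metStats$significant]
  if (length(sigProt) == 0L)
    warning("mergeLayers: no significant protein features")
  if (length(sigMet) == 0L)
    warning("mergeLayers: no significant metabolite features")

  pv <- t(intensities(prot)[sigProt, shared, drop = FALSE])
  mv <- t(intensities(met)[sigMet, shared, drop = FALSE])
  mv[mv == 0] <- NA_real_
  mv <- log(mv)
  values <- cbind(pv, mv)
  featureLayer <- c(rep("protein", length(sigProt)),
                    rep("metabolite", length(sigMet)))
  names(featureLayer) <- c(sigProt, sigMet)
  list(values = values, labels = gp, featureLayer = featureLayer)
}

# train size = round-half-down of ratio * n (13 * 0.7 -> 9)
roundHalfDown <- function(x) ceiling(x - 0.5)

#' Stratified train/test split
#'
#' Randomly partitions samples into a training and a test set at the given
#' ratio, with the training size rounded half-down (13 samples at 70:30
#' give 9 train / 4 test). The split is stratified so that each class
#' appears in both partitions whenever feasible, and is deterministic under
#' `seed`.
#'
#' @param sampleIds Character vector of sample ids.
#' @param labels Factor (or character) of class labels aligned with (or
#'   named by) `sampleIds`.
#' @param ratio Training proportion in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `trainIds` and `testIds`.
#' @examples
#' s <- paste0("S", 1:13)
#' g <- rep(c("control", "case"), c(6, 7))
#' sp <- splitTrainTest(s, g, 0.7, seed = 1)
#' lengths(sp)  # 9 and 4
#' @export
splitTrainTest <- function(sampleIds, labels, ratio = 0.7, seed = 1L) {
  stopifnot(ratio >= 0, ratio <= 1)
  if (!is.null(names(labels))) labels <- labels[sampleIds]
  labels <- as.character(labels)
  n <- length(sampleIds)
  trainSize <- roundHalfDown(ratio * n)
  classes <- sort(unique(labels))
  nc <- vapply(classes, function(cl) sum(labels == cl), integer(1))

  target <- roundHalfDown(ratio * nc)
  # keep each class in both partitions whenever feasible
  if (ratio > 0 && ratio < 1)
    target <- pmin(pmax(target, ifelse(nc >= 2L, 1L, 0L)), pmax(nc - 1L, 0L))
  # reconcile with the overall training size, preferring classes whose
  # fractional allocation was cut (or inflated) the most
  excess <- ratio * nc - target
  while (sum(target) < trainSize) {
    ok <- which(target < (if (ratio < 1) nc - 1L else nc))
    if (!length(ok)) ok <- which(target < nc)
    i <- ok[which.max(excess[ok])]
    target[i] <- target[i] + 1L
    excess[i] <- excess[i] - 1
  }
  while (sum(target) > trainSize) {
    ok <- which(target > (if (ratio > 0) 1L else 0L))
    if (!length(ok)) ok <- which(target > 0L)
    i <- ok[which.min(excess[ok])]
    target[i] <- target[i] - 1L
    excess[i] <- excess[i] + 1
  }

  train <- withSeed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      ids <- sampleIds[labels == classes[i]]
      sample(ids)[seq_len(target[i])]
    }))
  })
  trainIds <- sampleIds[sampleIds %in% train]
  testIds <- setdiff(sampleIds, trainIds)
  if (ratio > 0 && !all(classes %in% labels[sampleIds %in% trainIds]))
    stop("splitTrainTest: a class is absent from the training partition")
  list(trainIds = trainIds, testIds = testIds)
}

#' Learn and apply per-feature standardization
#'
#' `fitScaling()` estimates each feature's mean and standard deviation
#' (n - 1 denominator) on the training table only, ignoring missing values;
#' `applyScaling()` centres and scales any table with those parameters.
#' Constant (zero-variance) features are centred only and flagged.
#'
#' @param train Numeric samples x features matrix (training partition).
#' @return `fitScaling()`: a `data.frame` with columns `feature`, `mean`,
#'   `sd`, `constant`. `applyScaling()`: the transformed matrix.
#' @export
fitScaling <- function(train) {
  m <- apply(train, 2L, mean, na.rm = TRUE)
  s <- apply(train, 2L, stats::sd, na.rm = TRUE)
  constant <- !is.finite(s) | s == 0
  data.frame(feature = colnames(train), mean = unname(m),
             sd = unname(ifelse(constant, 1, s)),
             constant = unname(constant), stringsAsFactors = FALSE)
}

#' @param x Numeric samples x features matrix to transform.
#' @param scaling Result of [fitScaling()].
#' @rdname fitScaling
#' @export
applyScaling <- function(x, scaling) {
  idx <- match(colnames(x), scaling$feature)
  if (anyNA(idx))
    stop("applyScaling: scaling parameters missing for some features")
  sweep(sweep(x, 2L, scaling$mean[idx], "-"), 2L, scaling$sd[idx], "/")
}

#' K-nearest-neighbour imputation
#'
#' Fills each missing cell (sample s, feature f) with the mean of f over
#' the k donor samples nearest to s (Euclidean distance on mutually
#' observed features, normalised by the number of shared features), among
#' donors that observe f. k is truncated to the available donors; observed
#' cells are never altered. When no donor observes f the scaled mean 0 is
#' imputed and the feature is flagged in the `"imputedZero"` attribute.
#'
#' @param x Numeric samples x features matrix (already standardized).
#' @param k Number of neighbours.
#' @param donors Optional donor matrix with the same columns (e.g. the
#'   training partition when imputing test samples, so that no test-to-test
#'   leakage occurs). By default each sample's donors are the other rows
#'   of `x`.
#' @return The completed matrix.
#' @export
knnImpute <- function(x, k = 5L, donors = NULL) {
  selfPool <- is.null(donors)
  if (selfPool) donors <- x
  if (!identical(colnames(x), colnames(donors)))
    stop("knnImpute: donor matrix must share the feature columns")
  zeroImputed <- character()
  for (s in seq_len(nrow(x))) {
    missing <- which(is.na(x[s, ]))
    if (!length(missing)) next
    pool <- seq_len(nrow(donors))
    if (selfPool) pool <- setdiff(pool, s)
    d <- vapply(pool, function(j) {
      shared <- which(!is.na(x[s, ]) & !is.na(donors[j, ]))
      if (!length(shared)) return(Inf)
      sqrt(mean((x[s, shared] - donors[j, shared])^2))
    }, numeric(1))
    for (f in missing) {
      has <- which(!is.na(donors[pool, f]) & is.finite(d))
      if (!length(has)) {
        x[s, f] <- 0
        zeroImputed <- union(zeroImputed, colnames(x)[f])
        next
      }
      nearest <- has[order(d[has])][seq_len(min(k, length(has)))]
      x[s, f] <- mean(donors[pool[nearest], f])
    }
  }
  attr(x, "imputedZero") <- zeroImputed
  x
}

#' Build the integrated train/test dataset
#'
#' End-to-end integration step: merge the significant features of both
#' layers ([mergeLayers()]), split the shared samples 70:30 with
#' stratification ([splitTrainTest()]), learn per-feature scaling on the
#' training partition only ([fitScaling()]), transform both partitions,
#' and impute remaining missing values by K-nearest neighbours with the
#' training samples as donor pool ([knnImpute()]).
#'
#' @inheritParams mergeLayers
#' @param ratio Training proportion.
#' @param k Imputation neighbours.
#' @param seed Split seed.
#' @return An [IntegratedDataset-class].
#' @export
integrateLayers <- function(protStats, metStats, prot, met,
                            ratio = 0.7, k = 5L, seed = 1L) {
  merged <- mergeLayers(protStats, metStats, prot, met)
  split <- splitTrainTest(rownames(merged$values), merged$labels,
                          ratio = ratio, seed = seed)
  train <- merged$values[split$trainIds, , drop = FALSE]
  test <- merged$values[split$testIds, , drop = FALSE]
  scaling <- fitScaling(train)
  train <- knnImpute(applyScaling(train, scaling), k = k)
  test <- if (nrow(test))
    knnImpute(applyScaling(test, scaling), k = k, donors = train)
  else test
  attr(train, "imputedZero") <- NULL
  attr(test, "imputedZero") <- NULL
  new("IntegratedDataset",
      trainValues = train, testValues = test,
      trainIds = split$trainIds, testIds = split$testIds,
      labels = merged$labels, featureLayer = merged$featureLayer,
      scaling = scaling, imputationK = as.integer(k),
      seed = as.integer(seed))
}
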