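#' @include AllClasses.R
NULL

#' Accessors for integromics classes
#'
#' Small accessor generics: `layerType()` returns the layer tag of an
#' [OmicsLayer-class]; `sampleGroups()` its per-sample group factor;
#' `intensities()` the intensity assay; `selectedFeatures()` the chosen
#' feature ids of a [SelectionModel-class] (or the consensus panel of a
#' [ConsensusResult-class]); `cvAccuracy()` the cross-validated accuracy of
#' a fitted model; `accuracy()` the held-out accuracy of a
#' [ConfusionMatrix-class].
#'
#' @param x An object of the corresponding class.
#' @return See details per generic.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("layerType", function(x) standardGeneric("layerType"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
#' @export
setGeneric("cvAccuracy", function(x) standardGeneric("cvAccuracy"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setMethod("layerType", "OmicsLayer", function(x) x@layer)

#' @rdname accessors
#' @export
setMethod("sampleGroups", "OmicsLayer", function(x) {
  g <- colData(x)$group
  names(g) <- colnames(x)
  g
})

#' @rdname accessors
#' @export
setMethod("intensities", "OmicsLayer", function(x) assay(x, "intensity"))

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "SelectionModel", function(x) x@selected)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "ConsensusResult", function(x) x@consensusFeatures)

#' @rdname accessors
#' @export
setMethod("cvAccuracy", "ElasticNetModel", function(x) x@cvAccuracy)

#' @rdname accessors
#' @export
setMethod("cvAccuracy", "SelectionModel", function(x) x@cvAccuracy)

#' @rdname accessors
#' @export
setMethod("accuracy", "ConfusionMatrix", function(x) x@accuracy)

#' @describeIn OmicsLayer-class Compact display.
#' @param object An `OmicsLayer`.
#' @export
setMethod("show", "OmicsLayer", function(object) {
  g <- table(colData(object)$group)
  cat(sprintf("OmicsLayer (%s): %d features x %d samples [%d control, %d case]\n",
              object@layer, nrow(object), ncol(object),
              g[["control"]], g[["case"]]))
  miss <- mean(is.na(assay(object, "intensity")))
  cat(sprintf("  missing values: %.1f%%\n", 100 * miss))
})

#' @describeIn ConfusionMatrix-class Display as 2x2 table.
#' @param object A `ConfusionMatrix`.
#' @export
setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (positive class: case)\n")
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("case", "control"),
                              predicted = c("case", "control")))
  print(m)
  cat(sprintf("accuracy: %.3f\n", object@accuracy))
})

#' @describeIn ElasticNetModel-class Compact display.
#' @param object An `ElasticNetModel`.
#' @export
setMethod("show", "ElasticNetModel", function(object) {
  nz <- sum(object@coefficients != 0)
  cat(sprintf(
    "ElasticNetModel: alpha = %.2f, lambda = %.4g, %d/%d nonzero coefficients\n",
    object@alpha, object@lambda, nz, length(object@coefficients)))
  cat(sprintf("  CV accuracy: %.3f%s\n", object@cvAccuracy,
              if (object@looUsed) " (leave-one-out)" else ""))
})

#' @describeIn SelectionModel-class Compact display.
#' @param object A `SelectionModel`.
#' @export
setMethod("show", "SelectionModel", function(object) {
  cat(sprintf("SelectionModel [%s, size %d]: %s\n", object@algorithm,
              object@sizeParameter,
              paste(object@selected, collapse = ", ")))
  cat(sprintf("  resampled accuracy: %.3f\n", object@cvAccuracy))
})

#' @describeIn ConsensusResult-class Compact display.
#' @param object A `ConsensusResult`.
#' @export
setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf("ConsensusResult: %d source models, min occurrence %d\n",
              length(object@sourceModels), object@minOccurrence))
  cat(sprintf("  consensus panel (%d): %s\n", length(object@consensusFeatures),
              paste(object@consensusFeatures, collapse = ", ")))
  cat(sprintf("  test accuracy: %.3f\n", object@testConfusion@accuracy))
})
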