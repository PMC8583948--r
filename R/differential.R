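#' Filter features by missingness
#'
#' Features whose fraction of missing values across all samples exceeds
#' `maxMissing` are excluded from the statistical screen (the default drops
#' features with more than 50% missing values); feature order is preserved.
#'
#' @param x An [OmicsLayer-class].
#' @param maxMissing Maximum tolerated missing fraction in `[0, 1]`.
#' @return The filtered [OmicsLayer-class].
#' @export
filterMissing <- function(x, maxMissing = 0.5) {
  stopifnot(is(x, "OmicsLayer"), maxMissing >= 0, maxMissing <= 1)
  if (nrow(x) == 0L) return(x)
  frac <- rowMeans(is.na(intensities(x)))
  x[frac <= maxMissing, ]
}

#' Remove single outliers per feature and group
#'
#' Applies [dixonTest()] to the non-missing values of every feature within
#' each group independently; when the test is significant (`p < alpha`) the
#' candidate value is marked missing. At most one value is removed per
#' feature per group (single pass: Dixon's is a single-outlier test and
#' iterating it inflates removals). Features/groups where the test is
#' inapplicable (fewer than 3 values, all equal) are left untouched.
#'
#' @param x An [OmicsLayer-class].
#' @param alpha Significance level for removal.
#' @return A list with `matrix` (the [OmicsLayer-class] with removed values
#'   set to `NA`) and `removals` (a `data.frame` logging feature, sample,
#'   group, Q statistic and p-value of each removal).
#' @export
removeOutliers <- function(x, alpha = 0.05) {
  stopifnot(is(x, "OmicsLayer"))
  values <- intensities(x)
  group <- sampleGroups(x)
  log <- list()
  for (g in levels(group)) {
    cols <- which(group == g)
    for (f in seq_len(nrow(values))) {
      obs <- cols[!is.na(values[f, cols])]
      if (length(obs) < 3L) next
      res <- tryCatch(dixonTest(values[f, obs]),
                      dixonInapplicable = function(e) NULL)
      if (is.null(res) || res$pValue >= alpha) next
      victim <- obs[res$candidateIndex]
      log[[length(log) + 1L]] <- data.frame(
        feature_id = rownames(values)[f],
        sample_id = colnames(values)[victim],
        group = g, q_statistic = res$qStatistic, p_value = res$pValue,
        stringsAsFactors = FALSE)
      values[f, victim] <- NA_real_
    }
  }
  removals <- if (length(log)) do.call(rbind, log) else
    data.frame(feature_id = character(), sample_id = character(),
               group = character(), q_statistic = numeric(),
               p_value = numeric(), stringsAsFactors = FALSE)
  out <- x
  SummarizedExperiment::assay(out, "intensity") <- values
  list(matrix = out, removals = removals)
}

#' Mann-Whitney U test for one feature
#'
#' Two-sided rank-sum comparison of a feature between control and case
#' samples. The exact null distribution is used when both groups have at
#' most 8 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is applied. The
#' reported U counts (control, case) pairs with the control value larger.
#'
#' @param controlVals,caseVals Non-empty numeric vectors (missing values
#'   already removed).
#' @return List with elements `u` and `p`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitney <- function(controlVals, caseVals) {
  if (length(controlVals) == 0L || length(caseVals) == 0L)
    stop("mannWhitney: both groups must be non-empty")
  ties <- anyDuplicated(c(controlVals, caseVals)) > 0L
  exact <- !ties && length(controlVals) <= 8L && length(caseVals) <= 8L
  wt <- suppressWarnings(stats::wilcox.test(
    controlVals, caseVals, alternative = "two.sided",
    exact = exact, correct = TRUE))
  list(u = unname(wt$statistic), p = min(wt$p.value, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement,
#' capped at 1; input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("bhAdjust: p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold change (case over control)
#'
#' `log2(mean(case) / mean(control))` on the supplied (non-missing) values.
#' A zero group mean makes the ratio undefined and yields `NA`.
#'
#' @param controlVals,caseVals Numeric vectors.
#' @return Numeric scalar (possibly `NA`).
#' @export
log2FoldChange <- function(controlVals, caseVals) {
  mc <- mean(controlVals)
  mi <- mean(caseVals)
  if (!is.finite(mc) || !is.finite(mi) || mc <= 0 || mi <= 0) return(NA_real_)
  log2(mi / mc)
}

#' Per-layer differential-abundance screen
#'
#' Runs the full per-layer screen: missingness filter ([filterMissing()]),
#' per-group Dixon outlier removal ([removeOutliers()]), per-feature
#' Mann-Whitney U test ([mannWhitney()]), Benjamini-Hochberg adjustment
#' across all tested features of the layer ([bhAdjust()]) and log2 fold
#' change ([log2FoldChange()]). A feature is significant when its adjusted
#' p-value is below `fdr`. Features left with an empty group after removal
#' are untestable and excluded from the result.
#'
#' @param x An [OmicsLayer-class].
#' @param maxMissing Missingness threshold, see [filterMissing()].
#' @param alphaOutlier Dixon removal level, see [removeOutliers()].
#' @param fdr Adjusted-p significance threshold.
#' @return A [S4Vectors::DataFrame] with one row per tested feature:
#'   `feature_id`, `n_control_used`, `n_case_used`, `outliers_removed`
#'   (comma-separated sample ids), `u_statistic`, `p_value`, `p_adjusted`,
#'   `log2_fc`, `significant`. The layer tag and thresholds are kept in
#'   `metadata()`.
#' @export
runDifferential <- function(x, maxMissing = 0.5, alphaOutlier = 0.05,
                            fdr = 0.05) {
  stopifnot(is(x, "OmicsLayer"))
  filtered <- filterMissing(x, maxMissing)
  cleaned <- removeOutliers(filtered, alphaOutlier)
  values <- intensities(cleaned$matrix)
  group <- sampleGroups(cleaned$matrix)
  removals <- cleaned$removals

  rows <- lapply(seq_len(nrow(values)), function(f) {
    fid <- rownames(values)[f]
    ctrl <- values[f, group == "control"]
    case <- values[f, group == "case"]
    ctrl <- ctrl[!is.na(ctrl)]
    case <- case[!is.na(case)]
    if (length(ctrl) == 0L || length(case) == 0L) return(NULL)
    mw <- mannWhitney(ctrl, case)
    out <- removals$sample_id[removals$feature_id == fid]
    data.frame(
      feature_id = fid,
      n_control_used = length(ctrl), n_case_used = length(case),
      outliers_removed = paste(out, collapse = ","),
      u_statistic = mw$u, p_value = mw$p,
      log2_fc = log2FoldChange(ctrl, case),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    res <- S4Vectors::DataFrame(
      feature_id = character(), n_control_used = integer(),
      n_case_used = integer(), outliers_removed = character(),
      u_statistic = numeric(), p_value = numeric(),
      p_adjusted = numeric(), log2_fc = numeric(), significant = logical())
  } else {
    df <- do.call(rbind, rows)
    df$p_adjusted <- bhAdjust(df$p_value)
    df$significant <- df$p_adjusted < fdr
    res <- S4Vectors::DataFrame(
      df[, c("feature_id", "n_control_used", "n_case_used",
             "outliers_removed", "u_statistic", "p_value", "p_adjusted",
             "log2_fc", "significant")])
  }
  S4Vectors::metadata(res) <- list(layer = layerType(x),
                                   maxMissing = maxMissing,
                                   alphaOutlier = alphaOutlier, fdr = fdr)
  res
}

#' Collapse protein features to unique genes
#'
#' When several protein features map to the same gene, keeps the feature
#' with the smallest adjusted p-value per gene (ties: smallest raw p, then
#' lexicographic feature id). Features absent from `geneMap` are kept.
#'
#' @param stats Result of [runDifferential()].
#' @param geneMap Named character vector, feature id -> gene symbol.
#' @return The subset of `stats` with one representative per gene.
#' @export
collapseByGene <- function(stats, geneMap) {
  gene <- geneMap[stats$feature_id]
  unmapped <- is.na(gene)
  gene[unmapped] <- paste0(".feature:", stats$feature_id[unmapped])
  ord <- order(gene, stats$p_adjusted, stats$p_value, stats$feature_id)
  keep <- ord[!duplicated(gene[ord])]
  stats[sort(keep), ]
}

#' Write / read a differential result table as TSV
#'
#' @param stats Result of [runDifferential()].
#' @param path File path.
#' @return `writeFeatureStats()` invisibly returns `path`;
#'   `readFeatureStats()` returns a [S4Vectors::DataFrame].
#' @export
writeFeatureStats <- function(stats, path) {
  df <- as.data.frame(stats)
  names(df) <- c("feature_id", "n_control", "n_case", "outliers_removed",
                 "U", "p", "p_adj", "log2FC", "significant")
  writeTSV(df, path)
  invisible(path)
}

#' @rdname writeFeatureStats
#' @export
readFeatureStats <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("", "NA"))
  df$outliers_removed[is.na(df$outliers_removed)] <- ""
  names(df) <- c("feature_id", "n_control_used", "n_case_used",
                 "outliers_removed", "u_statistic", "p_value", "p_adjusted",
                 "log2_fc", "significant")
  S4Vectors::DataFrame(df)
}
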