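#' Construct an OmicsLayer
#'
#' Bundle a feature-by-sample intensity matrix with per-sample group labels
#' into an [OmicsLayer-class]. Intensities must be non-negative; missing
#' measurements are `NA`.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param group Character or factor vector over the samples with values
#'   `"control"`/`"case"`; either named by sample id or in column order.
#' @param layer `"protein"` or `"metabolite"`.
#' @return An [OmicsLayer-class].
#' @examples
#' m <- matrix(rlnorm(20), 4, 5,
#'             dimnames = list(paste0("F", 1:4), paste0("S", 1:5)))
#' OmicsLayer(m, c("control", "control", "case", "case", "case"), "protein")
#' @export
OmicsLayer <- function(values, group, layer = c("protein", "metabolite")) {
  layer <- match.arg(layer)
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("F", seq_len(nrow(values)))
  if (!is.null(names(group)))
    group <- group[colnames(values)]
  group <- factor(as.character(group), levels = c("control", "case"))
  se <- SummarizedExperiment(
    assays = list(intensity = values),
    colData = S4Vectors::DataFrame(group = group, row.names = colnames(values)))
  new("OmicsLayer", se, layer = layer)
}

#' Read / write an omics layer as TSV
#'
#' The values file has the feature id in its first column and one column per
#' sample; missing values are empty cells. The groups file has two columns:
#' sample id and group (`control` or `IVDH`/`case`; `IVDH` is mapped to
#' `case` on input).
#'
#' @param valuesFile,groupsFile File paths.
#' @param layer Layer tag, see [OmicsLayer()].
#' @return `readOmicsLayer()` returns an [OmicsLayer-class];
#'   `writeOmicsLayer()` invisibly returns the file paths.
#' @export
readOmicsLayer <- function(valuesFile, groupsFile,
                           layer = c("protein", "metabolite")) {
  layer <- match.arg(layer)
  tab <- read.delim(valuesFile, check.names = FALSE, na.strings = c("", "NA"))
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- as.character(tab[[1]])
  grp <- read.delim(groupsFile, check.names = FALSE,
                    colClasses = "character")
  g <- grp[[2]]
  g[g == "IVDH"] <- "case"
  names(g) <- grp[[1]]
  OmicsLayer(values, g, layer)
}

#' @param x An [OmicsLayer-class].
#' @param groupLabels How to encode the case group on output; the default
#'   `"IVDH"` matches the cohort labelling convention.
#' @rdname readOmicsLayer
#' @export
writeOmicsLayer <- function(x, valuesFile, groupsFile,
                            groupLabels = c(control = "control", case = "IVDH")) {
  stopifnot(is(x, "OmicsLayer"))
  v <- intensities(x)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE)
  writeTSV(df, valuesFile)
  g <- sampleGroups(x)
  writeTSV(data.frame(sample_id = names(g),
                      group = unname(groupLabels[as.character(g)])),
           groupsFile)
  invisible(c(valuesFile, groupsFile))
}
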