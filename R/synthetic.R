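#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design the package targets: a proteomic layer
#' with 6 control / 9 case samples and ~200 master-protein features, and a
#' metabolomic layer with 6 control / 7 case samples and ~80 identified
#' metabolite features; log-normal intensities; planted case-only effects
#' drawn uniformly from `effectLog2fcRange` (default -3.8 .. 2.5, the span
#' of reported fold changes); a share of non-planted features with >50%
#' missing values; and sporadic single-sample multiplicative outlier spikes.
#'
#' @param nControlProt,nCaseProt,nControlMet,nCaseMet Sample counts per
#'   group and layer. Control samples (and the leading case samples) share
#'   ids across layers, so the layers overlap on
#'   `min(nControlProt, nControlMet) + min(nCaseProt, nCaseMet)` samples.
#' @param nProteinFeatures,nMetaboliteFeatures Feature counts per layer.
#' @param nPlantedProt,nPlantedMet Number of features per layer given a
#'   genuine group effect.
#' @param effectLog2fcRange Length-2 numeric, low <= high; planted log2
#'   fold changes are drawn uniformly from this interval.
#' @param missingFractionFeatures Fraction of the non-planted features set
#'   missing in more than half of the samples (the mechanism targeted by
#'   the missingness filter).
#' @param outlierRate Per-feature probability of one sample being
#'   multiplied by `outlierFactor`.
#' @param outlierFactor Multiplicative spike size (>= 8).
#' @param noiseSdLog Residual SD on the natural-log scale.
#' @param seed Master seed; split deterministically into per-layer
#'   substreams.
#' @return A validated list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nControlProt = 6L, nCaseProt = 9L,
                            nControlMet = 6L, nCaseMet = 7L,
                            nProteinFeatures = 200L,
                            nMetaboliteFeatures = 80L,
                            nPlantedProt = 30L, nPlantedMet = 10L,
                            effectLog2fcRange = c(-3.8, 2.5),
                            missingFractionFeatures = 0.15,
                            outlierRate = 0.05,
                            outlierFactor = 10,
                            noiseSdLog = 0.5,
                            seed = 1L) {
  cfg <- list(
    nControlProt = as.integer(nControlProt), nCaseProt = as.integer(nCaseProt),
    nControlMet = as.integer(nControlMet), nCaseMet = as.integer(nCaseMet),
    nProteinFeatures = as.integer(nProteinFeatures),
    nMetaboliteFeatures = as.integer(nMetaboliteFeatures),
    nPlantedProt = as.integer(nPlantedProt),
    nPlantedMet = as.integer(nPlantedMet),
    effectLog2fcRange = as.numeric(effectLog2fcRange),
    missingFractionFeatures = as.numeric(missingFractionFeatures),
    outlierRate = as.numeric(outlierRate),
    outlierFactor = as.numeric(outlierFactor),
    noiseSdLog = as.numeric(noiseSdLog),
    seed = as.integer(seed))
  counts <- unlist(cfg[c("nControlProt", "nCaseProt", "nControlMet",
                         "nCaseMet", "nProteinFeatures",
                         "nMetaboliteFeatures", "nPlantedProt",
                         "nPlantedMet")])
  if (any(counts < 0L))
    stop("synthetic configuration: all counts must be >= 0")
  if (cfg$nPlantedProt > cfg$nProteinFeatures ||
      cfg$nPlantedMet > cfg$nMetaboliteFeatures)
    stop("synthetic configuration: planted features cannot exceed feature count")
  if (length(cfg$effectLog2fcRange) != 2L ||
      anyNA(cfg$effectLog2fcRange) ||
      cfg$effectLog2fcRange[1] > cfg$effectLog2fcRange[2])
    stop("synthetic configuration: effectLog2fcRange must be ordered low <= high")
  if (cfg$missingFractionFeatures < 0 || cfg$missingFractionFeatures > 1 ||
      cfg$outlierRate < 0 || cfg$outlierRate > 1)
    stop("synthetic configuration: proportions must lie in [0, 1]")
  if (cfg$noiseSdLog < 0)
    stop("synthetic configuration: noiseSdLog must be >= 0")
  if (cfg$outlierFactor < 8)
    stop("synthetic configuration: outlierFactor must be >= 8")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# One layer: log-normal baseline per feature, case-only planted effect,
# feature-level high missingness, sporadic single-sample spikes.
generateLayer <- function(layer, nFeat, nPlanted, nControl, nCase,
                          cfg, subseed) {
  prefix <- if (layer == "protein") "PROT" else "MET"
  featIds <- sprintf("%s%03d", prefix, seq_len(nFeat))
  sampleIds <- c(sprintf("C%02d", seq_len(nControl)),
                 sprintf("IVDH%02d", seq_len(nCase)))
  group <- factor(rep(c("control", "case"), c(nControl, nCase)),
                  levels = c("control", "case"))
  n <- nControl + nCase

  withSeed(subseed, {
    baseline <- stats::rnorm(nFeat, mean = log(1000), sd = 1)
    plantedIdx <- if (nPlanted > 0L) sort(sample.int(nFeat, nPlanted)) else integer()
    lfc <- stats::runif(nPlanted, cfg$effectLog2fcRange[1],
                        cfg$effectLog2fcRange[2])
    effect <- numeric(nFeat)
    effect[plantedIdx] <- lfc * log(2)
    caseInd <- as.numeric(group == "case")
    noise <- matrix(stats::rnorm(nFeat * n, 0, cfg$noiseSdLog), nFeat, n)
    values <- exp(baseline + outer(effect, caseInd) + noise)
    dimnames(values) <- list(featIds, sampleIds)

    # feature-level missingness on non-planted features: each affected
    # feature is blanked in floor(n/2)+1 random samples (> 50 %)
    nonPlanted <- setdiff(seq_len(nFeat), plantedIdx)
    nMissingFeat <- round(cfg$missingFractionFeatures * length(nonPlanted))
    missFeat <- if (nMissingFeat > 0L)
      sort(sample(nonPlanted, nMissingFeat)) else integer()
    nBlank <- floor(n / 2) + 1L
    for (f in missFeat)
      values[f, sample.int(n, nBlank)] <- NA_real_

    # single-sample multiplicative outlier spikes
    spiked <- which(stats::runif(nFeat) < cfg$outlierRate)
    for (f in spiked) {
      obs <- which(!is.na(values[f, ]))
      if (length(obs)) {
        j <- obs[sample.int(length(obs), 1L)]
        values[f, j] <- values[f, j] * cfg$outlierFactor
      }
    }

    truth <- data.frame(feature_id = featIds[plantedIdx],
                        layer = rep(layer, length(plantedIdx)),
                        planted_log2fc = lfc,
                        stringsAsFactors = FALSE)
    list(layer = OmicsLayer(values, group, layer), truth = truth)
  })
}

#' Generate a paired synthetic case-control cohort
#'
#' Draws a proteomic and a metabolomic [OmicsLayer-class] under the
#' generative model described in [syntheticConfig()], plus the ground truth
#' of planted effects. Per-sample intensities are
#' `exp(log baseline + planted_log2fc * ln(2) * I[case] + N(0, noiseSdLog))`;
#' identical seeds give bit-identical output.
#'
#' @param config A [syntheticConfig()].
#' @return A list with elements `protein` and `metabolite`
#'   ([OmicsLayer-class]), `truth` (a [S4Vectors::DataFrame] with columns
#'   `feature_id`, `layer`, `planted_log2fc`) and `config`.
#' @examples
#' cohort <- generateCohort(syntheticConfig(seed = 7))
#' cohort$protein
#' head(cohort$truth)
#' @export
generateCohort <- function(config = syntheticConfig()) {
  if (!inherits(config, "SyntheticConfig"))
    config <- do.call(syntheticConfig, config)
  seeds <- deriveSeeds(config$seed, 2L)
  prot <- generateLayer("protein", config$nProteinFeatures,
                        config$nPlantedProt, config$nControlProt,
                        config$nCaseProt, config, seeds[1])
  met <- generateLayer("metabolite", config$nMetaboliteFeatures,
                       config$nPlantedMet, config$nControlMet,
                       config$nCaseMet, config, seeds[2])
  truth <- S4Vectors::DataFrame(rbind(prot$truth, met$truth))
  list(protein = prot$layer, metabolite = met$layer,
       truth = truth, config = config)
}

#' Write a synthetic cohort to TSV files
#'
#' Writes each layer as a values + groups TSV pair (see
#' [writeOmicsLayer()]) and the ground truth as a three-column TSV.
#'
#' @param cohort Result of [generateCohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    writeOmicsLayer(cohort$protein,
                    file.path(dir, "protein_values.tsv"),
                    file.path(dir, "protein_groups.tsv")),
    writeOmicsLayer(cohort$metabolite,
                    file.path(dir, "metabolite_values.tsv"),
                    file.path(dir, "metabolite_groups.tsv")))
  truthPath <- file.path(dir, "ground_truth.tsv")
  writeTSV(as.data.frame(cohort$truth), truthPath)
  invisible(c(paths, truthPath))
}
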