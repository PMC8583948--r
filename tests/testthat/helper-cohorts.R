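# Shared fixture builders.

# Minimal layer from an explicit matrix.
makeLayer <- function(values, group, layer = "protein") {
  OmicsLayer(values, group, layer)
}

# Layer with named feature rows and a 6-control / 9-case design.
toyLayer <- function(nFeat = 10, seed = 1, layer = "protein",
                     nControl = 6, nCase = 9) {
  withr::local_seed(seed)
  v <- matrix(rlnorm(nFeat * (nControl + nCase), log(100), 0.3),
              nrow = nFeat,
              dimnames = list(sprintf("F%02d", seq_len(nFeat)),
                              c(sprintf("C%02d", seq_len(nControl)),
                                sprintf("IVDH%02d", seq_len(nCase)))))
  OmicsLayer(v, rep(c("control", "case"), c(nControl, nCase)), layer)
}

# Generator settings for the strong-signal recovery scenario: 6 planted
# features (4 proteins, 2 metabolites) at log2FC in [2, 2.5], low noise,
# on a screening-panel-sized feature space.
recoveryConfig <- function(seed) {
  syntheticConfig(nProteinFeatures = 60L, nMetaboliteFeatures = 30L,
                  nPlantedProt = 4L, nPlantedMet = 2L,
                  effectLog2fcRange = c(2, 2.5), noiseSdLog = 0.2,
                  missingFractionFeatures = 0.1, seed = seed)
}

# All-null cohort at the study's scale (200 protein features, no effects).
nullConfig <- function(seed) {
  syntheticConfig(nPlantedProt = 0L, nPlantedMet = 0L,
                  missingFractionFeatures = 0.15, seed = seed)
}
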