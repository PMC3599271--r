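#' @import methods
#' @importFrom stats lowess approx rnorm runif rbinom aov TukeyHSD pt qt
#'   var sd coef lm setNames aggregate
#' @importFrom utils read.delim write.table head
NULL

# round half away from zero, as printed tables in this field round
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# rbind a list of data.frames, dropping NULLs; NULL when nothing remains
rbindRows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Simulation configuration for synthetic confrontation experiments
#'
#' Holds every tunable of the synthetic-data generator: genome layout
#' (species, scaffolds, gene/intergenic sizes), tiling-array design
#' (probe length and spacing), regulation structure (fraction of genes
#' regulated per confrontation stage, effect sizes, planted genomic
#' clusters), measurement noise (probe noise, intensity-dependent dye
#' bias, non-detection rate), orthogroup sharing pattern and
#' conservation-class mixture.
#'
#' Defaults emulate a three-species confrontation experiment: 60-mer
#' probes every 93 bp, three stages (before contact, contact, after
#' contact) plus a self-confrontation control, two dye-swapped
#' replicates per condition.
#'
#' @slot seed integer RNG seed; identical configs give identical output.
#' @slot nSpecies number of species.
#' @slot scaffoldsPerSpecies scaffolds per species genome.
#' @slot genesPerScaffold genes per scaffold.
#' @slot geneLengthMean,geneLengthSpread gene length distribution (bp).
#' @slot intergenicMean,intergenicSpread intergenic gap distribution (bp).
#' @slot probeSpacing tiling step between probe starts (bp).
#' @slot probeLength probe length (bp).
#' @slot fracRegulated per-stage fraction of genes truly regulated.
#' @slot effectSize mean |log2 ratio| of regulated genes (> threshold).
#' @slot effectSpread sd of the |log2 ratio| draw.
#' @slot effectFloor lower truncation of |log2 ratio| draws.
#' @slot probeNoiseSd per-probe Gaussian noise sd (log2 units).
#' @slot dyeBiasAmplitude amplitude of the quadratic intensity-dependent
#'   dye bias (log2 units).
#' @slot fracUndetected Bernoulli probability a probe is flagged
#'   undetected on an array.
#' @slot nPlantedClusters planted genomic clusters per species.
#' @slot plantedClusterSize regulated genes per planted cluster (>= 3).
#' @slot plantedClusterMaxGap max ordinal gap between planted members.
#' @slot orthoSharing proportions of orthogroups present in exactly
#'   1, 2, ..., nSpecies species (sums to 1).
#' @slot classMix proportions of identified / unknown / orphan genes
#'   (sums to 1).
#' @slot speciesNames species labels.
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    nSpecies = "integer",
    scaffoldsPerSpecies = "integer",
    genesPerScaffold = "integer",
    geneLengthMean = "numeric",
    geneLengthSpread = "numeric",
    intergenicMean = "numeric",
    intergenicSpread = "numeric",
    probeSpacing = "integer",
    probeLength = "integer",
    fracRegulated = "numeric",
    effectSize = "numeric",
    effectSpread = "numeric",
    effectFloor = "numeric",
    probeNoiseSd = "numeric",
    dyeBiasAmplitude = "numeric",
    fracUndetected = "numeric",
    nPlantedClusters = "integer",
    plantedClusterSize = "integer",
    plantedClusterMaxGap = "integer",
    orthoSharing = "numeric",
    classMix = "numeric",
    speciesNames = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  prop <- c(fracRegulated = object@fracRegulated,
            fracUndetected = object@fracUndetected)
  bad <- prop < 0 | prop > 1
  if (any(bad))
    msg <- c(msg, sprintf("proportions outside [0,1]: %s",
                          paste(names(prop)[bad], collapse = ", ")))
  if (any(object@orthoSharing < 0) ||
      abs(sum(object@orthoSharing) - 1) > 1e-8)
    msg <- c(msg, "orthoSharing must be non-negative and sum to 1")
  if (length(object@orthoSharing) != object@nSpecies)
    msg <- c(msg, "orthoSharing must have one entry per species")
  if (any(object@classMix < 0) || abs(sum(object@classMix) - 1) > 1e-8)
    msg <- c(msg, "classMix must be non-negative and sum to 1")
  if (length(object@classMix) != 3L)
    msg <- c(msg, "classMix needs 3 entries (identified, unknown, orphan)")
  if (object@probeSpacing <= 0L) msg <- c(msg, "probeSpacing must be > 0")
  if (object@probeLength <= 0L) msg <- c(msg, "probeLength must be > 0")
  if (object@probeLength > object@probeSpacing)
    msg <- c(msg, "probe longer than probe spacing")
  if (object@plantedClusterSize < 3L)
    msg <- c(msg, "plantedClusterSize must be >= 3")
  if (object@plantedClusterMaxGap < 1L)
    msg <- c(msg, "plantedClusterMaxGap must be >= 1")
  if (length(object@speciesNames) != object@nSpecies)
    msg <- c(msg, "speciesNames must have one label per species")
  if (object@effectSize <= 1.5)
    msg <- c(msg, "effectSize must exceed the 1.5 regulation threshold")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed integer RNG seed.
#' @param nSpecies,scaffoldsPerSpecies,genesPerScaffold genome layout.
#' @param geneLengthMean,geneLengthSpread,intergenicMean,intergenicSpread
#'   gene/intergenic size distributions (bp).
#' @param probeSpacing,probeLength tiling design (bp).
#' @param fracRegulated,effectSize,effectSpread,effectFloor regulation
#'   structure.
#' @param probeNoiseSd,dyeBiasAmplitude,fracUndetected measurement model.
#' @param nPlantedClusters,plantedClusterSize,plantedClusterMaxGap planted
#'   genomic clusters.
#' @param orthoSharing proportions of orthogroups present in exactly
#'   1..nSpecies species.
#' @param classMix identified/unknown/orphan proportions.
#' @param speciesNames species labels.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, scaffoldsPerSpecies = 2,
#'                         genesPerScaffold = 40)
#' cfg
#' @export
simulationConfig <- function(seed = 1L,
                             nSpecies = 3L,
                             scaffoldsPerSpecies = 3L,
                             genesPerScaffold = 100L,
                             geneLengthMean = 1000,
                             geneLengthSpread = 150,
                             intergenicMean = 400,
                             intergenicSpread = 100,
                             probeSpacing = 93L,
                             probeLength = 60L,
                             fracRegulated = 0.025,
                             effectSize = 2.5,
                             effectSpread = 0.3,
                             effectFloor = 2.0,
                             probeNoiseSd = 0.3,
                             dyeBiasAmplitude = 0.5,
                             fracUndetected = 0.05,
                             nPlantedClusters = 2L,
                             plantedClusterSize = 4L,
                             plantedClusterMaxGap = 1L,
                             orthoSharing = c(0.2, 0.2, 0.6),
                             classMix = c(identified = 0.66,
                                          unknown = 0.334,
                                          orphan = 0.006),
                             speciesNames = NULL) {
  nSpecies <- as.integer(nSpecies)
  if (is.null(speciesNames)) {
    speciesNames <- if (nSpecies <= 3L) c("Ta", "Tv", "Tr")[seq_len(nSpecies)]
                    else paste0("sp", seq_len(nSpecies))
  }
  new("SimulationConfig",
      seed = as.integer(seed),
      nSpecies = nSpecies,
      scaffoldsPerSpecies = as.integer(scaffoldsPerSpecies),
      genesPerScaffold = as.integer(genesPerScaffold),
      geneLengthMean = geneLengthMean,
      geneLengthSpread = geneLengthSpread,
      intergenicMean = intergenicMean,
      intergenicSpread = intergenicSpread,
      probeSpacing = as.integer(probeSpacing),
      probeLength = as.integer(probeLength),
      fracRegulated = fracRegulated,
      effectSize = effectSize,
      effectSpread = effectSpread,
      effectFloor = effectFloor,
      probeNoiseSd = probeNoiseSd,
      dyeBiasAmplitude = dyeBiasAmplitude,
      fracUndetected = fracUndetected,
      nPlantedClusters = as.integer(nPlantedClusters),
      plantedClusterSize = as.integer(plantedClusterSize),
      plantedClusterMaxGap = as.integer(plantedClusterMaxGap),
      orthoSharing = orthoSharing,
      classMix = classMix,
      speciesNames = speciesNames)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat(sprintf("  %d species (%s), %d scaffolds x %d genes each\n",
              object@nSpecies, paste(object@speciesNames, collapse = ", "),
              object@scaffoldsPerSpecies, object@genesPerScaffold))
  cat(sprintf("  probes: %d-mers every %d bp; noise sd %.2f, dye bias %.2f, undetected %.2f\n",
              object@probeLength, object@probeSpacing, object@probeNoiseSd,
              object@dyeBiasAmplitude, object@fracUndetected))
  cat(sprintf("  regulation: %.3f per stage, effect %.2f; %d planted clusters of %d\n",
              object@fracRegulated, object@effectSize,
              object@nPlantedClusters, object@plantedClusterSize))
  cat(sprintf("  seed %d\n", object@seed))
})

#' Synthetic confrontation experiment container
#'
#' Result of [simulateConfrontation()]: per-species gene catalogs
#' (GRanges), orthogroup map, conservation-hit and FunCat tables, the
#' probe-level measurement table, plate/qPCR assay tables, and the
#' planted ground truth (held separately; pipeline stages never read it).
#'
#' @slot config the [SimulationConfig-class] used.
#' @slot catalogs named list of GRanges gene catalogs (one per species).
#' @slot orthogroups data.frame (group_id, species, gene_id).
#' @slot hits data.frame conservation-hit table (BLAST tabular style).
#' @slot funcat data.frame FunCat assignments.
#' @slot probes data.frame probe-level measurements, all species/stages.
#' @slot assays list with `plates`, `qpcr`, `dilution` data.frames.
#' @slot truth list of ground-truth tables (effects, regulated, clusters,
#'   classes, assay truths).
#' @export
setClass("ConfrontationSim",
  representation(
    config = "SimulationConfig",
    catalogs = "list",
    orthogroups = "data.frame",
    hits = "data.frame",
    funcat = "data.frame",
    probes = "data.frame",
    assays = "list",
    truth = "list"
  )
)

setMethod("show", "ConfrontationSim", function(object) {
  ng <- vapply(object@catalogs, length, integer(1))
  cat("ConfrontationSim\n")
  cat(sprintf("  species: %s\n",
              paste(sprintf("%s (%d genes)", names(ng), ng), collapse = ", ")))
  cat(sprintf("  %d probe measurements across stages %s\n",
              nrow(object@probes),
              paste(unique(object@probes$stage), collapse = ", ")))
  cat(sprintf("  %d orthogroups; %d planted regulated gene-stage pairs\n",
              length(unique(object@orthogroups$group_id)),
              nrow(object@truth$regulated)))
})

#' @describeIn ConfrontationSim-class gene catalogs (named list of GRanges)
#' @param x a ConfrontationSim
#' @export
geneCatalogs <- function(x) x@catalogs

#' @describeIn ConfrontationSim-class probe measurement table
#' @export
probeMeasurements <- function(x) x@probes

#' @describeIn ConfrontationSim-class orthogroup map
#' @export
orthoGroups <- function(x) x@orthogroups

#' @describeIn ConfrontationSim-class planted ground truth (tests only)
#' @export
groundTruth <- function(x) x@truth

#' @describeIn ConfrontationSim-class the generating configuration
#' @export
simConfig <- function(x) x@config

#' Expected-spacing model for genomic cluster scanning
#'
#' Under uniform random placement, one regulated gene is expected per
#' batch of S = nTotal/nReg consecutive genes. Genes are considered
#' clustered when consecutive regulated genes are at least 3-fold closer
#' than this expectation, i.e. when ordinal gaps are at most floor(S/3).
#'
#' @slot nTotal genes in the genome.
#' @slot nReg regulated genes.
#' @slot S expected batch size (rounded per `roundMode`).
#' @slot maxGap maximum ordinal gap inside a cluster, floor(S/3).
#' @slot minCluster minimum regulated genes per reported cluster (3).
#' @slot foldThreshold density enrichment threshold (3).
#' @slot roundMode rounding convention used for S.
#' @export
setClass("SpacingModel",
  representation(
    nTotal = "integer",
    nReg = "integer",
    S = "integer",
    maxGap = "integer",
    minCluster = "integer",
    foldThreshold = "numeric",
    roundMode = "character"
  )
)

setValidity("SpacingModel", function(object) {
  msg <- character()
  if (object@S < 1L) msg <- c(msg, "S must be >= 1")
  if (object@minCluster < 3L) msg <- c(msg, "minCluster must be >= 3")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpacingModel", function(object) {
  cat(sprintf(
    "SpacingModel: %d genes / %d regulated -> S = %d (%s), maxGap = %d, minCluster = %d, fold >= %.1f\n",
    object@nTotal, object@nReg, object@S, object@roundMode,
    object@maxGap, object@minCluster, object@foldThreshold))
})
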