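#' @importFrom GenomicRanges GRanges findOverlaps seqnames strand start end
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

STAGES <- c("BC", "C", "AC")
CONTROL_STAGE <- "CTRL"

# largest-remainder apportionment: integer counts matching proportions exactly
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# small FunCat-style vocabulary used by the generator
funcatVocabulary <- function() {
  data.frame(
    funcat_number = c("01_25_03", "01_25_01", "01_20_05_11", "01_20_36",
                      "20_03", "16_21", "11_02_03_04", "70_27",
                      "32_01_05", "32_07_07_03", "30_05_02_24", "16_21_07"),
    label = c("protease", "GH glycosyl hydrolase", "PKS", "NRPS",
              "MFS (major facilitator superfamily)",
              "cytochrome P450 subfamily",
              "Zn2Cys6 transcriptional regulator",
              "SSCR (small secreted cysteine rich protein)",
              "chaperone/heat shock protein",
              "glutathione S-transferase",
              "PTH11-type GPCR",
              "short chain dehydrogenase/reductase"),
    stringsAsFactors = FALSE
  )
}

#' Generate per-species gene catalogs with orthology and conservation tables
#'
#' Lays out genes on scaffolds (lengths and intergenic gaps drawn from the
#' configured distributions, strands random, 1-based ordinals by coordinate
#' order), builds an orthogroup map whose species-presence pattern follows
#' `orthoSharing`, draws a conservation-hit table whose E-values reproduce
#' the configured identified/unknown/orphan mixture exactly under
#' [classifyConservation()], and assigns FunCat categories to a subset of
#' identified genes.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `catalogs` (named list of GRanges, mcols
#'   `gene_id`, `ordinal`), `orthogroups`, `hits`, `funcat` and
#'   `classTruth` data.frames.
#' @export
simulateGeneCatalogs <- function(config) {
  validObject(config)
  set.seed(config@seed)
  minLen <- max(2L * config@probeLength,
                round(config@geneLengthMean - 2 * config@geneLengthSpread))

  catalogs <- list()
  classRows <- list()
  hitRows <- list()
  funRows <- list()
  vocab <- funcatVocabulary()

  for (sp in config@speciesNames) {
    grs <- list()
    for (sc in seq_len(config@scaffoldsPerSpecies)) {
      n <- config@genesPerScaffold
      lens <- pmax(round(rnorm(n, config@geneLengthMean,
                               config@geneLengthSpread)), minLen)
      gaps <- pmax(round(rnorm(n, config@intergenicMean,
                               config@intergenicSpread)), 50)
      starts <- cumsum(c(gaps[1], lens[-n] + gaps[-1])) + 1
      ends <- starts + lens - 1
      scaf <- sprintf("%s_sc%d", sp, sc)
      gr <- GRanges(scaf, IRanges(starts, ends),
                    strand = sample(c("+", "-"), n, replace = TRUE))
      mcols(gr)$gene_id <- sprintf("%s_s%02dg%04d", sp, sc, seq_len(n))
      mcols(gr)$ordinal <- seq_len(n)
      seqlengths(gr)[scaf] <- max(ends) + round(config@intergenicMean)
      grs[[scaf]] <- gr
    }
    cat <- suppressWarnings(do.call(c, unname(grs)))
    catalogs[[sp]] <- cat

    # conservation classes: exact mixture via largest remainder
    ids <- mcols(cat)$gene_id
    counts <- apportion(length(ids), config@classMix)
    cls <- sample(rep(c("identified", "unknown", "orphan"), counts))
    classRows[[sp]] <- data.frame(species = sp, gene_id = ids, class = cls,
                                  stringsAsFactors = FALSE)

    hitRows[[sp]] <- simulateHits(sp, ids, cls)

    # FunCat assignments for a subset of identified genes
    idg <- ids[cls == "identified"]
    withF <- idg[runif(length(idg)) < 0.6]
    if (length(withF)) {
      rows <- sample(nrow(vocab), length(withF), replace = TRUE)
      funRows[[sp]] <- data.frame(species = sp, gene_id = withF,
                                  funcat_number = vocab$funcat_number[rows],
                                  label = vocab$label[rows],
                                  stringsAsFactors = FALSE)
    }
  }

  list(catalogs = catalogs,
       orthogroups = simulateOrthogroups(config, catalogs),
       hits = rbindRows(hitRows),
       funcat = rbindRows(funRows),
       classTruth = rbindRows(classRows))
}

# conservation-hit table: E-values consistent with the intended class.
# Every gene also gets a congeneric (Trichoderma) hit that the classifier
# must ignore.
simulateHits <- function(sp, ids, cls) {
  n <- length(ids)
  rows <- vector("list", 4)
  rows[[1]] <- data.frame(
    species = sp, qseqid = ids,
    sseqid = sprintf("Trichoderma_sp_%s", ids),
    evalue = 10^-runif(n, 120, 180),
    is_trichoderma = TRUE, is_sordariomycete = TRUE, is_pezizomycotina = TRUE,
    stringsAsFactors = FALSE)
  idn <- ids[cls == "identified"]
  if (length(idn))
    rows[[2]] <- data.frame(
      species = sp, qseqid = idn,
      sseqid = paste0("Fusarium_oxysporum_", seq_along(idn)),
      evalue = 10^-runif(length(idn), 101, 180),
      is_trichoderma = FALSE, is_sordariomycete = TRUE,
      is_pezizomycotina = TRUE, stringsAsFactors = FALSE)
  unk <- ids[cls == "unknown"]
  if (length(unk))
    rows[[3]] <- data.frame(
      species = sp, qseqid = unk,
      sseqid = paste0("Aspergillus_nidulans_", seq_along(unk)),
      evalue = 10^-runif(length(unk), 21, 95),
      is_trichoderma = FALSE, is_sordariomycete = FALSE,
      is_pezizomycotina = TRUE, stringsAsFactors = FALSE)
  # half the orphans have a weak (non-qualifying) hit, half none at all
  orp <- ids[cls == "orphan"]
  orp <- orp[runif(length(orp)) < 0.5]
  if (length(orp))
    rows[[4]] <- data.frame(
      species = sp, qseqid = orp,
      sseqid = paste0("Aspergillus_weak_", seq_along(orp)),
      evalue = 10^-runif(length(orp), 0, 15),
      is_trichoderma = FALSE, is_sordariomycete = FALSE,
      is_pezizomycotina = TRUE, stringsAsFactors = FALSE)
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# orthogroup map: each group's species-presence count k drawn from
# orthoSharing; members popped from per-species shuffled gene pools
simulateOrthogroups <- function(config, catalogs) {
  nsp <- config@nSpecies
  pools <- lapply(catalogs, function(g) sample(mcols(g)$gene_id))
  nGroups <- floor(0.7 * min(vapply(pools, length, integer(1))))
  used <- integer(nsp); names(used) <- names(pools)
  out <- vector("list", nGroups)
  for (i in seq_len(nGroups)) {
    k <- sample.int(nsp, 1, prob = config@orthoSharing)
    spp <- sort(sample.int(nsp, k))
    gid <- sprintf("OG%05d", i)
    mem <- lapply(spp, function(s) {
      used[[s]] <<- used[[s]] + 1L
      pools[[s]][used[[s]]]
    })
    out[[i]] <- data.frame(group_id = gid,
                           species = names(pools)[spp],
                           gene_id = unlist(mem),
                           stringsAsFactors = FALSE)
  }
  rbindRows(out)
}

# quadratic intensity-dependent dye bias, mean ~ 0 over A ~ U(8, 16)
dyeBias <- function(A, amplitude) {
  z <- (A - 12) / 4
  amplitude * (z^2 - 1 / 3)
}

#' Generate probe-level two-colour measurements with planted ground truth
#'
#' Tiles every scaffold on both strands at `probeSpacing`, plants regulated
#' genes (including genomic clusters of regulated genes) per confrontation
#' stage, and simulates dye-swapped replicate pairs of log2 ratios: probes
#' fully inside a regulated gene on the matching strand carry the gene's
#' true effect, all probes carry additive Gaussian noise and a quadratic
#' intensity-dependent dye bias, and a configurable fraction is flagged
#' undetected. The dye-swapped replicate has the sign-inverted true ratio
#' before bias. A self-confrontation control condition (true ratio 0
#' everywhere) is generated alongside the three stages.
#'
#' @param config a [SimulationConfig-class].
#' @param catalogs named list of GRanges gene catalogs
#'   (from [simulateGeneCatalogs()]).
#' @return list with `probes` (data.frame: species, probe_id, scaffold,
#'   start, end in 0-based half-open coordinates, strand, stage, replicate,
#'   dye_swapped, A, M, detected) and `truth` (list: `regulated`,
#'   `effects`, `clusters`).
#' @export
simulateProbeData <- function(config, catalogs) {
  validObject(config)
  if (config@probeLength > config@probeSpacing)
    stopf("probe longer than probe spacing")
  set.seed(config@seed + 1L)

  regRows <- list(); cluRows <- list(); probeRows <- list()

  for (sp in names(catalogs)) {
    cat <- catalogs[[sp]]
    truth <- plantRegulation(config, cat, sp)
    regRows[[sp]] <- truth$regulated
    cluRows[[sp]] <- truth$clusters

    probes <- tileScaffolds(config, cat)
    pGR <- GRanges(probes$scaffold,
                   IRanges(probes$start + 1L, probes$end),
                   strand = probes$strand)
    ov <- findOverlaps(pGR, cat, type = "within")
    # probe -> gene map (non-overlapping genes: at most one hit per probe)
    probeGene <- rep(NA_character_, nrow(probes))
    probeGene[queryHits(ov)] <- mcols(cat)$gene_id[subjectHits(ov)]

    nP <- nrow(probes)
    arrays <- expand.grid(stage = c(STAGES, CONTROL_STAGE), replicate = 1:2,
                          stringsAsFactors = FALSE)
    spRows <- vector("list", nrow(arrays))
    for (a in seq_len(nrow(arrays))) {
      st <- arrays$stage[a]; rp <- arrays$replicate[a]
      trueM <- numeric(nP)
      if (st %in% STAGES) {
        eff <- truth$effectMap[[st]]      # named: gene_id -> true log2
        hit <- !is.na(probeGene) & probeGene %in% names(eff)
        trueM[hit] <- eff[probeGene[hit]]
      }
      A <- runif(nP, 8, 16)
      sgn <- if (rp == 2L) -1 else 1
      M <- sgn * trueM + dyeBias(A, config@dyeBiasAmplitude) +
        rnorm(nP, 0, config@probeNoiseSd)
      spRows[[a]] <- data.frame(
        species = sp, probe_id = probes$probe_id,
        scaffold = probes$scaffold, start = probes$start, end = probes$end,
        strand = probes$strand, stage = st, replicate = rp,
        dye_swapped = rp == 2L, A = A, M = M,
        detected = runif(nP) >= config@fracUndetected,
        stringsAsFactors = FALSE)
    }
    probeRows[[sp]] <- do.call(rbind, spRows)
  }

  regulated <- rbindRows(regRows)
  clusters <- rbindRows(cluRows)
  list(probes = rbindRows(probeRows),
       truth = list(regulated = regulated,
                    effects = regulated[, c("species", "gene_id", "stage",
                                            "true_log2")],
                    clusters = clusters))
}

# tile one species' scaffolds on both strands; BED-like 0-based half-open
tileScaffolds <- function(config, cat) {
  sl <- seqlengths(cat)
  rows <- lapply(names(sl), function(scaf) {
    len <- sl[[scaf]]
    starts1 <- seq.int(1L, len - config@probeLength + 1L,
                       by = config@probeSpacing)
    data.frame(
      scaffold = scaf,
      start = rep(starts1 - 1L, 2L),
      end = rep(starts1 - 1L + config@probeLength, 2L),
      strand = rep(c("+", "-"), each = length(starts1)),
      stringsAsFactors = FALSE)
  })
  probes <- do.call(rbind, rows)
  probes$probe_id <- sprintf("%s:%d:%s", probes$scaffold, probes$start,
                             probes$strand)
  probes
}

# plant per-stage regulated genes and genomic clusters for one species
plantRegulation <- function(config, cat, sp) {
  genes <- data.frame(gene_id = mcols(cat)$gene_id,
                      scaffold = as.character(seqnames(cat)),
                      ordinal = mcols(cat)$ordinal,
                      stringsAsFactors = FALSE)
  scafs <- unique(genes$scaffold)
  usedOrd <- lapply(scafs, function(x) integer(0)); names(usedOrd) <- scafs

  cluRows <- list()
  regList <- list()
  for (ci in seq_len(config@nPlantedClusters)) {
    scaf <- scafs[((ci - 1L) %% length(scafs)) + 1L]
    nOrd <- sum(genes$scaffold == scaf)
    gaps <- sample.int(config@plantedClusterMaxGap,
                       config@plantedClusterSize - 1L, replace = TRUE)
    span <- sum(gaps)
    for (try in 1:50) {
      first <- sample.int(nOrd - span, 1)
      ords <- first + c(0L, cumsum(gaps))
      if (!any(ords %in% usedOrd[[scaf]])) break
    }
    usedOrd[[scaf]] <- c(usedOrd[[scaf]], ords)
    stage <- sample(STAGES, 1)
    gids <- genes$gene_id[genes$scaffold == scaf & genes$ordinal %in% ords]
    cluRows[[ci]] <- data.frame(species = sp, scaffold = scaf,
                                first_ordinal = min(ords),
                                last_ordinal = max(ords),
                                size = length(ords), stage = stage,
                                gene_ids = paste(gids, collapse = ","),
                                stringsAsFactors = FALSE)
    regList[[length(regList) + 1L]] <- data.frame(
      species = sp, gene_id = gids, stage = stage, direction = "up",
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, regList)

  # top up each stage with randomly placed regulated genes
  nPerStage <- round(config@fracRegulated * nrow(genes))
  for (st in STAGES) {
    have <- planted$gene_id[planted$stage == st]
    need <- max(0L, nPerStage - length(have))
    pool <- setdiff(genes$gene_id, have)
    if (need > 0L && length(pool)) {
      pick <- sample(pool, min(need, length(pool)))
      regList[[length(regList) + 1L]] <- data.frame(
        species = sp, gene_id = pick, stage = st,
        direction = sample(c("up", "down"), length(pick), replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  regulated <- rbindRows(regList)
  mag <- pmax(rnorm(nrow(regulated), config@effectSize, config@effectSpread),
              config@effectFloor)
  regulated$true_log2 <- ifelse(regulated$direction == "up", mag, -mag)

  effectMap <- lapply(setNames(STAGES, STAGES), function(st) {
    r <- regulated[regulated$stage == st, ]
    setNames(r$true_log2, r$gene_id)
  })
  list(regulated = regulated,
       clusters = rbindRows(cluRows),
       effectMap = effectMap)
}

#' Generate confrontation-plate and qPCR assay tables
#'
#' The plate table holds, per species, the plug distance, radial growth of
#' the prey toward a self-confrontation control and toward the
#' confronting species, and the overgrowth extent over the prey colony;
#' the defaults emulate the three contrasting antagonism outcomes
#' (stimulation, inhibition with predation, near-complete overgrowth).
#' The qPCR table holds target and normalizer (tef1) Ct values for
#' treatment and control with known true fold changes, plus a cDNA
#' dilution series (1, 0.1, 1e-2, 1e-3) with known amplification
#' efficiency.
#'
#' @param config a [SimulationConfig-class].
#' @param efficiency true amplification efficiency (1 = perfect doubling).
#' @param ctNoiseSd Gaussian noise sd on generated Ct values (cycles).
#' @param trueInhibition,trueOvergrowth per-species true percentages
#'   (recycled over species).
#' @return list with `plates`, `qpcr`, `dilution` data.frames and `truth`.
#' @export
simulateAssayData <- function(config, efficiency = 1.0, ctNoiseSd = 0.1,
                              trueInhibition = c(0, 9, -21),
                              trueOvergrowth = c(86, 100, 15)) {
  validObject(config)
  set.seed(config@seed + 2L)
  sp <- config@speciesNames
  inh <- rep_len(trueInhibition, length(sp))
  og <- rep_len(trueOvergrowth, length(sp))

  plug <- 60; gSelf <- 30; depth <- 30
  plates <- data.frame(
    species = sp, prey = "R_solani",
    plug_distance = plug,
    growth_self = gSelf,
    growth_confronted = gSelf * (1 - inh / 100),
    overgrowth_extent = depth * pmin(og, 100) / 100,
    prey_colony_depth = depth,
    stringsAsFactors = FALSE)

  targets <- data.frame(
    gene = c("gh16_1", "prot1", "pks1", "sscp1", "nox1", "mfs1"),
    log2fc = c(3, 2.5, 2, 1.8, -2, 0),
    stringsAsFactors = FALSE)
  base <- log2(1 + efficiency)
  grid <- expand.grid(gene = c(targets$gene, "tef1"),
                      condition = c("treatment", "control"),
                      replicate = 1:3, stringsAsFactors = FALSE)
  grid$role <- ifelse(grid$gene == "tef1", "normalizer", "target")
  ct0 <- ifelse(grid$role == "normalizer", 20, 24)
  fc <- setNames(targets$log2fc, targets$gene)
  shift <- ifelse(grid$role == "target" & grid$condition == "treatment",
                  fc[grid$gene] / base, 0)
  grid$Ct <- ct0 - ifelse(is.na(shift), 0, shift) +
    rnorm(nrow(grid), 0, ctNoiseSd)
  qpcr <- grid[, c("gene", "role", "condition", "replicate", "Ct")]

  dil <- expand.grid(gene = c("tef1", targets$gene[1]),
                     dilution = c(1, 0.1, 1e-2, 1e-3),
                     replicate = 1:3, stringsAsFactors = FALSE)
  dil$Ct <- 20 - log10(dil$dilution) / log10(1 + efficiency) +
    rnorm(nrow(dil), 0, ctNoiseSd)

  list(plates = plates, qpcr = qpcr, dilution = dil,
       truth = list(inhibition = setNames(inh, sp),
                    overgrowth = setNames(pmin(og, 100), sp),
                    qpcrLog2 = fc, efficiency = efficiency))
}

#' Simulate a complete confrontation experiment
#'
#' Runs [simulateGeneCatalogs()], [simulateProbeData()] and
#' [simulateAssayData()] under one configuration and bundles the results.
#' Identical configurations (including seed) produce identical objects.
#'
#' @param config a [SimulationConfig-class].
#' @param ... passed to [simulateAssayData()].
#' @return a [ConfrontationSim-class] object.
#' @examples
#' sim <- simulateConfrontation(simulationConfig(seed = 7,
#'   scaffoldsPerSpecies = 2, genesPerScaffold = 40))
#' sim
#' @export
simulateConfrontation <- function(config = simulationConfig(), ...) {
  cats <- simulateGeneCatalogs(config)
  pr <- simulateProbeData(config, cats$catalogs)
  as <- simulateAssayData(config, ...)
  truth <- c(pr$truth,
             list(classes = cats$classTruth, assays = as$truth))
  new("ConfrontationSim", config = config, catalogs = cats$catalogs,
      orthogroups = cats$orthogroups, hits = cats$hits,
      funcat = cats$funcat, probes = pr$probes,
      assays = as[c("plates", "qpcr", "dilution")], truth = truth)
}
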