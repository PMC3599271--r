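test_that("identical configs give identical simulations", {
  cfg <- tinyConfig(seed = 5)
  s1 <- simulateConfrontation(cfg)
  s2 <- simulateConfrontation(cfg)
  expect_identical(probeMeasurements(s1), probeMeasurements(s2))
  expect_identical(orthoGroups(s1), orthoGroups(s2))
  expect_identical(groundTruth(s1), groundTruth(s2))
  expect_identical(lapply(geneCatalogs(s1), as.data.frame),
                   lapply(geneCatalogs(s2), as.data.frame))
})

test_that("config validity rejects bad parameter combinations", {
  expect_error(simulationConfig(orthoSharing = c(0.5, 0.6, 0.2)),
               "sum to 1")
  expect_error(simulationConfig(fracUndetected = 1.5), "proportions")
  expect_error(simulationConfig(probeLength = 120, probeSpacing = 93),
               "longer than")
  expect_error(simulationConfig(plantedClusterSize = 2), ">= 3")
})

test_that("gene catalogs are coordinate-ordered with 1-based ordinals", {
  cats <- simulateGeneCatalogs(tinyConfig())$catalogs
  for (gr in cats) {
    df <- as.data.frame(gr)
    for (sc in unique(df$seqnames)) {
      sub <- df[df$seqnames == sc, ]
      expect_identical(sub$ordinal, seq_len(nrow(sub)))
      expect_true(all(diff(sub$start) > 0))
      expect_true(all(sub$end >= sub$start))
    }
  }
})

test_that("degenerate class mixture labels every gene identified", {
  cfg <- tinyConfig(classMix = c(1, 0, 0))
  out <- simulateGeneCatalogs(cfg)
  ids <- S4Vectors::mcols(out$catalogs[[1]])$gene_id
  cls <- classifyConservation(out$hits[out$hits$species == "Ta", ], ids)
  expect_true(all(cls == "identified"))
})

test_that("classifier recovers the declared class mixture exactly", {
  cfg <- tinyConfig(seed = 9)
  out <- simulateGeneCatalogs(cfg)
  for (sp in names(out$catalogs)) {
    ids <- S4Vectors::mcols(out$catalogs[[sp]])$gene_id
    cls <- classifyConservation(out$hits[out$hits$species == sp, ], ids)
    truth <- out$classTruth[out$classTruth$species == sp, ]
    expect_identical(unname(cls[truth$gene_id]), truth$class)
  }
})

test_that("orthogroup sharing pattern follows configured proportions", {
  cfg <- simulationConfig(seed = 21, scaffoldsPerSpecies = 4,
                          genesPerScaffold = 120,
                          orthoSharing = c(0.2, 0.3, 0.5))
  og <- simulateGeneCatalogs(cfg)$orthogroups
  sizes <- table(table(og$group_id))
  nG <- length(unique(og$group_id))
  frac3 <- as.integer(sizes["3"]) / nG
  # binomial sampling error around 0.5 at nG groups
  expect_lt(abs(frac3 - 0.5), 3 * sqrt(0.5 * 0.5 / nG))
  expect_true(all(!duplicated(paste(og$species, og$gene_id))))
})

test_that("probe tiling matches the closed-form position count", {
  cfg <- simulationConfig()
  gr <- GenomicRanges::GRanges("s1", IRanges::IRanges(1, 500))
  S4Vectors::mcols(gr)$gene_id <- "g1"
  S4Vectors::mcols(gr)$ordinal <- 1L
  GenomeInfoDb::seqlengths(gr) <- c(s1 = 10000)
  p <- mycotrans:::tileScaffolds(cfg, gr)
  expectPositions <- floor((10000 - 60) / 93) + 1
  expect_equal(sum(p$strand == "+"), expectPositions)
  expect_equal(p$start[1], 0)           # 0-based BED-like
  expect_equal(p$end[1] - p$start[1], 60)
  expect_equal(p$start[2] - p$start[1], 93)
})

test_that("noise-free probes inside regulated genes carry the exact effect", {
  cfg <- tinyConfig(probeNoiseSd = 0, dyeBiasAmplitude = 0,
                    fracUndetected = 0)
  cats <- simulateGeneCatalogs(cfg)
  pd <- simulateProbeData(cfg, cats$catalogs)
  tr <- pd$truth$regulated
  r1 <- tr[1, ]
  cat1 <- cats$catalogs[[r1$species]]
  g <- cat1[S4Vectors::mcols(cat1)$gene_id == r1$gene_id]
  pr <- pd$probes
  inside <- pr$species == r1$species & pr$stage == r1$stage &
    pr$replicate == 1 &
    pr$scaffold == as.character(GenomicRanges::seqnames(g)) &
    pr$start + 1 >= GenomicRanges::start(g) &
    pr$end <= GenomicRanges::end(g) &
    pr$strand == as.character(GenomicRanges::strand(g))
  expect_gt(sum(inside), 0)
  expect_equal(unique(pr$M[inside]), r1$true_log2)
  # dye-swapped replicate carries the sign-inverted ratio
  swapped <- pr[pr$species == r1$species & pr$stage == r1$stage &
                  pr$replicate == 2, ]
  probeIds <- pr$probe_id[inside]
  expect_equal(unique(swapped$M[swapped$probe_id %in% probeIds]),
               -r1$true_log2)
  # control condition is null everywhere
  expect_true(all(pr$M[pr$stage == "CTRL"] == 0))
})

test_that("planted cluster members are regulated and effects exceed threshold", {
  pd <- simulateProbeData(tinyConfig(), simulateGeneCatalogs(tinyConfig())$catalogs)
  tr <- pd$truth
  expect_true(all(abs(tr$regulated$true_log2) > 1.5))
  cluGenes <- unlist(strsplit(tr$clusters$gene_ids, ","))
  expect_true(all(cluGenes %in% tr$regulated$gene_id))
})

test_that("total non-detection leads to all transcripts discarded", {
  cfg <- tinyConfig(fracUndetected = 1)
  cats <- simulateGeneCatalogs(cfg)
  pd <- simulateProbeData(cfg, cats$catalogs)
  pr <- pd$probes[pd$probes$species == "Ta", ]
  suppressWarnings(
    q <- quantifyExpression(pr, cats$catalogs[["Ta"]], stages = "BC"))
  expect_true(all(q$calls$regulation == "discarded"))
})

test_that("assay generator encodes the configured truths", {
  cfg <- tinyConfig()
  as0 <- simulateAssayData(cfg, efficiency = 1, ctNoiseSd = 0)
  pm <- plateMetrics(as0$plates)
  expect_equal(pm$inhibition_pct,
               unname(as0$truth$inhibition[pm$species]))
  expect_equal(pm$overgrowth_pct,
               unname(as0$truth$overgrowth[pm$species]))
  # null fold change at efficiency 1 gives Livak ratio exactly 1
  as1 <- simulateAssayData(cfg, efficiency = 1, ctNoiseSd = 0)
  qq <- qpcrQuantify(as1$qpcr)
  expect_equal(qq$fold[qq$gene == "mfs1"], 1)
  # dilution-series slope is -1/log10(2) at efficiency 1
  fit <- efficiencyFromDilution(as1$dilution$Ct, as1$dilution$dilution)
  expect_equal(fit$slope, -1 / log10(2), tolerance = 1e-10)
})
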