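test_that("expected batch sizes reproduce the genome arithmetic", {
  expect_equal(expectedSpacing(11865, 651)@S, 18L)
  expect_equal(expectedSpacing(9143, 424)@S, 22L)
  expect_equal(expectedSpacing(12518, 303, roundMode = "ceiling")@S, 42L)
  m <- expectedSpacing(200, 10)
  expect_equal(m@S, 20L)
  expect_equal(m@maxGap, 6L)
  expect_error(expectedSpacing(100, 0), "nReg")
})

test_that("chain scan reports maximal gap-limited runs with area and density", {
  m <- expectedSpacing(11865, 651)  # S = 18, maxGap = 6
  cl <- scanClusters(c(44, 45, 47), m)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$area, "44-47")
  expect_equal(cl$density, "3/4")
  cl2 <- scanClusters(c(10, 14, 19, 40, 90, 95, 101), m)
  expect_equal(cl2$area, c("10-19", "90-101"))
  expect_equal(cl2$density, c("3/10", "3/12"))
  # gaps beyond maxGap break every chain
  expect_equal(nrow(scanClusters(c(10, 20, 30), m)), 0)
  expect_error(scanClusters(c(5, 500), m, scaffoldGenes = 100), "exceeds")
})

test_that("scan equals exhaustive window enumeration on random scaffolds", {
  set.seed(33)
  for (i in 1:200) {
    nGenes <- sample(20:200, 1)
    nReg <- sample(3:min(30, nGenes), 1)
    S <- sample(4:60, 1)
    m <- expectedSpacing(S * 100, 100)   # gives S exactly
    ords <- sort(sample.int(nGenes, nReg))
    got <- scanClusters(ords, m, nGenes)
    want <- oracleClusterWindows(ords, S)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$members,
                   vapply(want, paste, "", collapse = ","))
    }
  }
})

test_that("every emitted cluster is at least 3-fold enriched (chain-rule theorem)", {
  set.seed(34)
  for (i in 1:2000) {
    S <- sample(3:80, 1)
    m <- expectedSpacing(S * 50, 50)
    nG <- sample(30:300, 1)
    ords <- sort(sample.int(nG, sample(3:min(40, nG), 1)))
    cl <- scanClusters(ords, m)
    if (nrow(cl)) {
      expect_true(all(cl$fold >= m@foldThreshold))
      expect_true(all(cl$n >= 3))
      # maximality: gaps to neighbours outside each cluster exceed maxGap
      for (k in seq_len(nrow(cl))) {
        mem <- as.integer(strsplit(cl$members[k], ",")[[1]])
        before <- ords[ords < min(mem)]
        after <- ords[ords > max(mem)]
        if (length(before)) expect_gt(min(mem) - max(before), m@maxGap)
        if (length(after)) expect_gt(min(after) - max(mem), m@maxGap)
      }
    }
  }
})

test_that("published density fixtures satisfy the spacing invariants", {
  # representative (members, span, S) cluster rows at batch sizes 18/42/22
  fix <- rbind(c(3, 4, 18), c(7, 19, 18), c(10, 13, 18), c(3, 10, 18),
               c(6, 36, 42), c(4, 17, 42), c(7, 25, 42), c(10, 11, 42),
               c(3, 7, 22), c(5, 20, 22), c(7, 30, 22), c(6, 28, 22))
  for (i in seq_len(nrow(fix))) {
    n <- fix[i, 1]; span <- fix[i, 2]; S <- fix[i, 3]
    expect_gte(n, 3)
    expect_lte(span, 1 + (n - 1) * floor(S / 3))   # gap-compatible
    expect_gte((n / span) * S, 3)                  # >= 3-fold enrichment
  }
})

test_that("genome scan flags scaffold-end clusters and summarizes fractions", {
  cfg <- tinyConfig(seed = 37)
  cats <- simulateGeneCatalogs(cfg)
  genes <- cats$catalogs[["Ta"]]
  gdf <- as.data.frame(genes)
  # regulate ordinals 1-7 on scaffold 1 (end) and 15-21 mid-scaffold 2
  reg <- c(gdf$gene_id[gdf$seqnames == gdf$seqnames[1]][c(1, 3, 5, 7)],
           gdf$gene_id[gdf$seqnames == unique(gdf$seqnames)[2]][c(15, 17, 19)])
  m <- expectedSpacing(80, 8)   # S = 10, maxGap = 3
  cl <- scanGenomeClusters(genes, reg, m, endWindow = 0.25)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$at_end, c(TRUE, FALSE))
  s <- clusterSummary(cl, 7)
  expect_equal(s$n_clustered_genes, 7)
  expect_equal(s$nonrandom_pct, 100)
  expect_equal(s$end_fraction, 0.5)
  expect_error(scanGenomeClusters(genes, "nope", m), "absent")
  # arithmetic example: member counts 3, 7, 4 of 100 regulated genes
  expect_equal(clusterSummary(data.frame(n = c(3, 7, 4),
                                         at_end = rep(FALSE, 3)),
                              100)$nonrandom_pct, 14.0)
  empty <- clusterSummary(scanClusters(integer(), m), 10)
  expect_equal(empty$nonrandom_pct, 0)
  expect_true(is.na(empty$end_fraction))
})

test_that("permutation null is deterministic and calibrated at the extremes", {
  m <- expectedSpacing(200, 20)   # S = 10
  # nothing clustered: p must be exactly 1
  p0 <- permutationNull(list(s1 = c(10, 50, 90, 130)), c(s1 = 200), m,
                        nPerm = 200, seed = 1)
  expect_equal(p0$observed_fraction, 0)
  expect_equal(p0$p_value, 1)
  # tight planted cluster: small p, reproducible under the same seed
  dense <- list(s1 = c(20, 21, 22, 23, 24, 25))
  p1 <- permutationNull(dense, c(s1 = 500), m, nPerm = 500, seed = 2)
  p2 <- permutationNull(dense, c(s1 = 500), m, nPerm = 500, seed = 2)
  expect_identical(p1$p_value, p2$p_value)
  expect_lte(p1$p_value, 0.01)
  expect_equal(p1$observed_fraction, 1)
})

test_that("planted clusters are recovered when their members are called", {
  cfg <- simulationConfig(seed = 41, scaffoldsPerSpecies = 2,
                          genesPerScaffold = 40, nPlantedClusters = 2)
  sim <- simulateConfrontation(cfg)
  tr <- groundTruth(sim)
  for (sp in simConfig(sim)@speciesNames) {
    genes <- geneCatalogs(sim)[[sp]]
    reg <- unique(tr$regulated$gene_id[tr$regulated$species == sp])
    m <- expectedSpacing(length(genes), length(reg))
    cl <- scanGenomeClusters(genes, reg, m)
    plant <- tr$clusters[tr$clusters$species == sp, ]
    for (k in seq_len(nrow(plant))) {
      hit <- cl$scaffold == plant$scaffold[k] &
        cl$first <= plant$first_ordinal[k] &
        cl$last >= plant$last_ordinal[k]
      expect_true(any(hit))
    }
  }
})
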