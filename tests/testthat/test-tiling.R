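test_that("flag filtering removes exactly the undetected probes", {
  df <- data.frame(probe_id = sprintf("p%d", 1:10),
                   detected = rep(c(TRUE, FALSE), c(7, 3)))
  out <- discardFlagged(df)
  expect_equal(nrow(out$probes), 7)
  expect_equal(out$nDiscarded, 3)
  allDet <- discardFlagged(data.frame(probe_id = "p", detected = TRUE))
  expect_equal(nrow(allDet$probes), 1)
  expect_warning(none <- discardFlagged(data.frame(detected = c(FALSE, FALSE))),
                 "all probes")
  expect_equal(nrow(none$probes), 0)
  expect_error(discardFlagged(data.frame(M = 1)), "detected")
})

test_that("Lowess normalization is a no-op on flat data and removes shifts", {
  set.seed(1)
  A <- runif(500, 8, 16)
  M0 <- rep(0, 500)
  expect_equal(lowessNormalize(M0, A), M0, tolerance = 1e-12)
  # constant shift is removed exactly (local regression is linear in M)
  M <- rnorm(500, 0, 0.2)
  expect_equal(lowessNormalize(M + 0.5, A), lowessNormalize(M, A),
               tolerance = 1e-6)
  expect_error(lowessNormalize(rnorm(5), runif(5)), "fewer than 10")
})

test_that("Lowess removes simulator-injected quadratic dye bias", {
  cfg <- tinyConfig(seed = 3, dyeBiasAmplitude = 1.0)
  pd <- simulateProbeData(cfg, simulateGeneCatalogs(cfg)$catalogs)
  arr <- pd$probes[pd$probes$species == "Ta" & pd$probes$stage == "BC" &
                     pd$probes$replicate == 1 & pd$probes$detected, ]
  expect_gt(residualTrend(arr$M, arr$A), 0.2)    # bias is really there
  norm <- lowessNormalize(arr$M, arr$A)
  expect_lt(residualTrend(norm, arr$A), 0.05)
})

test_that("dye-swap merging averages sign-corrected ratios with fallbacks", {
  r1 <- data.frame(probe_id = c("a", "b", "c"), M = c(2.0, 1.8, 1.0),
                   detected = c(TRUE, TRUE, TRUE))
  r2 <- data.frame(probe_id = c("a", "b", "c"), M = c(-2.0, -2.2, 0.5),
                   detected = c(TRUE, TRUE, FALSE))
  m <- mergeDyeSwap(r1, r2)
  expect_equal(m$M[m$probe_id == "a"], 2.0)
  expect_equal(m$M[m$probe_id == "b"], 2.0)
  expect_equal(m$M[m$probe_id == "c"], 1.0)   # single-replicate fallback
  expect_true(m$single_replicate[m$probe_id == "c"])
  expect_error(mergeDyeSwap(r1, r2[1:2, ]), "reconcile")
})

test_that("probe-gene assignment needs strict containment and matching strand", {
  genes <- GenomicRanges::GRanges("s1", IRanges::IRanges(50, 500), strand = "+")
  S4Vectors::mcols(genes)$gene_id <- "g1"
  probe <- function(start, end, strand)
    data.frame(probe_id = "p", scaffold = "s1", start = start, end = end,
               strand = strand)
  expect_equal(nrow(mapProbesToGenes(probe(100, 160, "+"), genes)), 1)
  expect_equal(nrow(mapProbesToGenes(probe(100, 160, "-"), genes)), 0)
  expect_equal(nrow(mapProbesToGenes(probe(480, 540, "+"), genes)), 0)
  # 0-based start 49 is 1-based 50: still contained
  expect_equal(nrow(mapProbesToGenes(probe(49, 109, "+"), genes)), 1)
  expect_error(mapProbesToGenes(probe(1, 61, "+") |>
                                  transform(scaffold = "sX"), genes), "sX")
  # a probe inside two overlapping same-strand genes counts for both
  genes2 <- GenomicRanges::GRanges("s1", IRanges::IRanges(c(50, 80), c(500, 600)),
                                   strand = "+")
  S4Vectors::mcols(genes2)$gene_id <- c("g1", "g2")
  expect_equal(sort(mapProbesToGenes(probe(100, 160, "+"), genes2)$gene_id),
               c("g1", "g2"))
})

test_that("transcript aggregation means detected probes and discards <=1", {
  merged <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                       M = c(1.2, 1.8, 2.4, 9, 9),
                       detected = c(TRUE, TRUE, TRUE, FALSE, TRUE))
  asg <- data.frame(probe_id = c("p1", "p2", "p3", "p4", "p5"),
                    gene_id = c("gA", "gA", "gA", "gB", "gB"))
  out <- aggregateTranscripts(merged, asg, c("gA", "gB", "gC"))
  expect_equal(out$log2_ratio[out$gene_id == "gA"], 1.8)
  expect_equal(out$regulation[out$gene_id == "gA"], "up")
  # gB has only one detected probe, gC none: both discarded
  expect_equal(out$regulation[out$gene_id == "gB"], "discarded")
  expect_equal(out$regulation[out$gene_id == "gC"], "discarded")
  expect_true(all((out$n_probes_detected <= 1) ==
                    (out$regulation == "discarded")))
})

test_that("regulation calls use strict threshold inequalities", {
  expect_equal(callRegulation(c(1.6, -1.6, 1.5, -1.5, 0)),
               c("up", "down", "none", "none", "none"))
  expect_error(callRegulation(NaN), "non-finite")
})

test_that("pipeline aggregation agrees with a brute-force probe scan", {
  cfg <- tinyConfig(seed = 13)
  cats <- simulateGeneCatalogs(cfg)
  pd <- simulateProbeData(cfg, cats$catalogs)
  sp <- "Tv"
  genes <- cats$catalogs[[sp]]
  pr <- pd$probes[pd$probes$species == sp, ]
  q <- quantifyExpression(pr, genes, stages = "C")

  # rebuild the merged table exactly as the pipeline does, then hand-scan
  reps <- lapply(1:2, function(rp) {
    arr <- pr[pr$stage == "C" & pr$replicate == rp & pr$detected, ]
    arr$M <- lowessNormalize(arr$M, arr$A)
    arr
  })
  ids <- unique(pr$probe_id)
  t1 <- data.frame(probe_id = ids, M = reps[[1]]$M[match(ids, reps[[1]]$probe_id)])
  t2 <- data.frame(probe_id = ids, M = reps[[2]]$M[match(ids, reps[[2]]$probe_id)])
  t1$detected <- !is.na(t1$M); t2$detected <- !is.na(t2$M)
  t1$M[is.na(t1$M)] <- 0; t2$M[is.na(t2$M)] <- 0
  merged <- mergeDyeSwap(t1, t2)

  gdf <- as.data.frame(genes)
  genesDf <- data.frame(gene_id = gdf$gene_id, scaffold = gdf$seqnames,
                        start = gdf$start, end = gdf$end,
                        strand = gdf$strand, stringsAsFactors = FALSE)
  coords <- unique(pr[, c("probe_id", "scaffold", "start", "end", "strand")])
  pick <- genesDf[seq(1, nrow(genesDf), by = 7), ]   # subsample for speed
  oracle <- oracleAggregate(merged, coords, pick)
  got <- q$calls[match(pick$gene_id, q$calls$gene_id), ]
  expect_equal(unname(got$n_probes_detected), unname(oracle$n[pick$gene_id]))
  ok <- got$n_probes_detected > 1
  expect_equal(unname(got$log2_ratio[ok]),
               unname(oracle$mean[pick$gene_id][ok]), tolerance = 1e-12)
})

test_that("call categories partition the gene universe per stage", {
  cfg <- tinyConfig(seed = 17)
  cats <- simulateGeneCatalogs(cfg)
  pd <- simulateProbeData(cfg, cats$catalogs)
  genes <- cats$catalogs[["Ta"]]
  q <- quantifyExpression(pd$probes[pd$probes$species == "Ta", ], genes)
  for (st in unique(q$calls$stage)) {
    sub <- q$calls[q$calls$stage == st, ]
    expect_equal(nrow(sub), length(genes))
    expect_equal(sum(table(sub$regulation)), length(genes))
  }
})

test_that("negating every probe ratio swaps up and down calls exactly", {
  cfg <- tinyConfig(seed = 19)
  cats <- simulateGeneCatalogs(cfg)
  pd <- simulateProbeData(cfg, cats$catalogs)
  genes <- cats$catalogs[["Ta"]]
  pr <- pd$probes[pd$probes$species == "Ta", ]
  q1 <- quantifyExpression(pr, genes, stages = "AC")
  pr$M <- -pr$M
  q2 <- quantifyExpression(pr, genes, stages = "AC")
  expect_gt(sum(q1$calls$regulation == "up") +
              sum(q1$calls$regulation == "down"), 0)
  expect_equal(q1$calls$regulation == "up", q2$calls$regulation == "down")
  expect_equal(q1$calls$regulation == "down", q2$calls$regulation == "up")
  expect_equal(q1$calls$log2_ratio, -q2$calls$log2_ratio, tolerance = 1e-9)
})
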