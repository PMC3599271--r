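# Independent brute-force oracles, deliberately written with different
# algorithms/data structures than the implementation they check.

# exhaustive enumeration of maximal qualifying windows over regulated
# ordinals: window o[i..j] qualifies if every consecutive gap <= maxGap
# and it has >= minCluster members; report windows not extendable either way
oracleClusterWindows <- function(ordinals, S,
                                 maxGap = max(1L, floor(S / 3)),
                                 minCluster = 3L) {
  o <- sort(unique(as.integer(ordinals)))
  n <- length(o)
  out <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 < minCluster) next
      gaps <- diff(o[i:j])
      if (length(gaps) && any(gaps > maxGap)) next
      leftOk <- i == 1 || (o[i] - o[i - 1]) > maxGap
      rightOk <- j == n || (o[j + 1] - o[j]) > maxGap
      if (leftOk && rightOk)
        out[[length(out) + 1L]] <- o[i:j]
    }
  }
  out
}

# brute-force per-gene mean of detected, strand-matched, fully contained
# probes; direct coordinate comparison, no interval machinery
oracleAggregate <- function(mergedProbes, probeCoords, genesDf) {
  mM <- setNames(mergedProbes$M, mergedProbes$probe_id)
  mDet <- setNames(mergedProbes$detected, mergedProbes$probe_id)
  res <- numeric(0); cnt <- integer(0)
  for (k in seq_len(nrow(genesDf))) {
    g <- genesDf[k, ]
    contained <- probeCoords$scaffold == g$scaffold &
      probeCoords$strand == g$strand &
      probeCoords$start + 1 >= g$start &
      probeCoords$end <= g$end
    ids <- probeCoords$probe_id[contained]
    ids <- ids[!is.na(mDet[ids]) & mDet[ids] & is.finite(mM[ids])]
    res[g$gene_id] <- if (length(ids)) mean(mM[ids]) else NA_real_
    cnt[g$gene_id] <- length(ids)
  }
  list(mean = res, n = cnt)
}

# brute-force Venn region counts over orthogroups + singleton genes
oracleVenn <- function(involved, orthogroups, species) {
  counts <- list()
  bump <- function(region) {
    counts[[region]] <<- (counts[[region]] %||% 0L) + 1L
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  invKey <- paste(involved$species, involved$gene_id)
  for (gid in unique(orthogroups$group_id)) {
    mem <- orthogroups[orthogroups$group_id == gid, ]
    spp <- unique(mem$species[paste(mem$species, mem$gene_id) %in% invKey])
    if (!length(spp)) next
    bump(paste(species[species %in% spp], collapse = "&"))
  }
  ogKey <- paste(orthogroups$species, orthogroups$gene_id)
  for (i in seq_len(nrow(involved))) {
    if (!(paste(involved$species[i], involved$gene_id[i]) %in% ogKey))
      bump(involved$species[i])
  }
  unlist(counts)
}

tinyConfig <- function(seed = 11, ...) {
  simulationConfig(seed = seed, scaffoldsPerSpecies = 2,
                   genesPerScaffold = 40, nPlantedClusters = 1, ...)
}

# small deterministic call table builder
makeCalls <- function(gene_id, stage, log2_ratio,
                      regulation = callRegulation(log2_ratio),
                      n = 5L) {
  data.frame(gene_id = gene_id, stage = stage, log2_ratio = log2_ratio,
             n_probes_detected = n, regulation = regulation,
             stringsAsFactors = FALSE)
}
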