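#' Expected-spacing model for regulated genes
#'
#' Under uniform random placement one regulated gene is expected per
#' batch of S = nTotal/nReg consecutive genes. Genes count as clustered
#' when their local spacing is at least 3-fold tighter, operationalized
#' as ordinal gaps of at most floor(S/3).
#'
#' @param nTotal total genes in the genome.
#' @param nReg regulated genes.
#' @param roundMode rounding of S: `"round"` (half-up, default),
#'   `"floor"` or `"ceiling"`.
#' @param minCluster minimum members per reported cluster.
#' @param foldThreshold density-enrichment threshold.
#' @return a [SpacingModel-class].
#' @examples
#' expectedSpacing(11865, 651)  # S = 18
#' expectedSpacing(9143, 424)   # S = 22
#' @export
expectedSpacing <- function(nTotal, nReg,
                            roundMode = c("round", "floor", "ceiling"),
                            minCluster = 3L, foldThreshold = 3.0) {
  roundMode <- match.arg(roundMode)
  if (nReg < 1) stopf("nReg must be >= 1")
  S <- switch(roundMode,
              round = floor(nTotal / nReg + 0.5),
              floor = floor(nTotal / nReg),
              ceiling = ceiling(nTotal / nReg))
  new("SpacingModel", nTotal = as.integer(nTotal), nReg = as.integer(nReg),
      S = as.integer(S), maxGap = as.integer(max(1L, floor(S / 3))),
      minCluster = as.integer(minCluster), foldThreshold = foldThreshold,
      roundMode = roundMode)
}

# chain scan on one scaffold's sorted regulated ordinals
chainScan <- function(ordinals, model) {
  o <- sort(unique(as.integer(ordinals)))
  if (!length(o)) return(list())
  brk <- which(diff(o) > model@maxGap)
  starts <- c(1L, brk + 1L)
  ends <- c(brk, length(o))
  lapply(which(ends - starts + 1L >= model@minCluster), function(i)
    o[starts[i]:ends[i]])
}

#' Scan a scaffold for density clusters of regulated genes
#'
#' Chains consecutive regulated genes whose ordinal gap is at most
#' `maxGap = floor(S/3)`; maximal chains with at least `minCluster`
#' members are reported with their gene-number area, density
#' (members/span) and fold enrichment `(members/span) * S`. By
#' construction every reported cluster is at least `foldThreshold`-fold
#' denser than the genome-wide expectation.
#'
#' @param ordinals integer vector of regulated gene ordinals (1-based
#'   gene numbers on one scaffold).
#' @param model a [SpacingModel-class].
#' @param scaffoldGenes total genes on the scaffold (for bounds checking
#'   and scaffold-end calls); NA skips the check.
#' @return data.frame: `first`, `last`, `n`, `span`, `area` ("a-b"),
#'   `density` ("n/span"), `fold`, `members` (comma-joined ordinals).
#' @examples
#' m <- expectedSpacing(11865, 651)
#' scanClusters(c(44, 45, 47), m)  # area 44-47, density 3/4
#' @export
scanClusters <- function(ordinals, model, scaffoldGenes = NA_integer_) {
  if (length(ordinals) && any(ordinals < 1))
    stopf("ordinals must be >= 1")
  if (!is.na(scaffoldGenes) && length(ordinals) &&
      any(ordinals > scaffoldGenes))
    stopf("ordinal exceeds scaffold gene count (%d)", scaffoldGenes)
  chains <- chainScan(ordinals, model)
  rows <- lapply(chains, function(m) {
    first <- m[1]; last <- m[length(m)]
    span <- last - first + 1L
    n <- length(m)
    data.frame(first = first, last = last, n = n, span = span,
               area = sprintf("%d-%d", first, last),
               density = sprintf("%d/%d", n, span),
               fold = (n / span) * model@S,
               members = paste(m, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- rbindRows(rows)
  if (is.null(out))
    out <- data.frame(first = integer(), last = integer(), n = integer(),
                      span = integer(), area = character(),
                      density = character(), fold = numeric(),
                      members = character(), stringsAsFactors = FALSE)
  out
}

#' Genome-wide cluster scan over a gene catalog
#'
#' Runs [scanClusters()] per scaffold on the ordinals of the regulated
#' genes and flags clusters at scaffold ends.
#'
#' @param genes GRanges gene catalog (mcols `gene_id`, `ordinal`).
#' @param regulatedIds character vector of regulated gene ids.
#' @param model a [SpacingModel-class].
#' @param endWindow fraction of a scaffold's gene count that counts as
#'   its "end" (a cluster touching the first or last window is at an
#'   end).
#' @return data.frame with `scaffold`, the [scanClusters()] columns and
#'   `at_end`.
#' @export
scanGenomeClusters <- function(genes, regulatedIds, model,
                               endWindow = 0.1) {
  unknown <- setdiff(regulatedIds, mcols(genes)$gene_id)
  if (length(unknown))
    stopf("regulated gene ids absent from catalog: %s",
          paste(head(unknown, 5), collapse = ", "))
  df <- data.frame(scaffold = as.character(seqnames(genes)),
                   gene_id = mcols(genes)$gene_id,
                   ordinal = mcols(genes)$ordinal,
                   stringsAsFactors = FALSE)
  reg <- df[df$gene_id %in% regulatedIds, ]
  rows <- lapply(unique(df$scaffold), function(sc) {
    nGenes <- sum(df$scaffold == sc)
    cl <- scanClusters(reg$ordinal[reg$scaffold == sc], model, nGenes)
    if (!nrow(cl)) return(NULL)
    w <- max(1L, floor(endWindow * nGenes))
    cl$at_end <- cl$first <= w | cl$last > nGenes - w
    cbind(data.frame(scaffold = sc, stringsAsFactors = FALSE), cl)
  })
  out <- rbindRows(rows)
  if (is.null(out))
    out <- cbind(data.frame(scaffold = character(), stringsAsFactors = FALSE),
                 scanClusters(integer(), model), at_end = logical())
  out
}

#' Summarize a cluster scan
#'
#' @param clusters data.frame from [scanGenomeClusters()].
#' @param nReg number of regulated genes in the genome.
#' @return list: `n_clusters`, `n_clustered_genes`, `nonrandom_pct`
#'   (percent of regulated genes inside clusters, one decimal),
#'   `end_fraction` (clusters at scaffold ends / clusters; NA when no
#'   clusters).
#' @examples
#' m <- expectedSpacing(200, 20)
#' cl <- data.frame(n = c(3, 7, 4), at_end = c(TRUE, FALSE, FALSE))
#' clusterSummary(cl, 100)$nonrandom_pct  # 14.0
#' @export
clusterSummary <- function(clusters, nReg) {
  nc <- nrow(clusters)
  ng <- if (nc) sum(clusters$n) else 0L
  list(n_clusters = nc,
       n_clustered_genes = ng,
       nonrandom_pct = roundHalfUp(100 * ng / nReg, 1),
       end_fraction = if (nc) sum(clusters$at_end) / nc else NA_real_)
}

#' Permutation null for the clustered-gene fraction
#'
#' Permutes the regulated labels uniformly over gene ordinals within each
#' scaffold, rescans, and compares the fraction of regulated genes inside
#' clusters with the observed fraction. The p-value uses the add-one
#' convention `(1 + #(perm >= obs)) / (nPerm + 1)`.
#'
#' @param regulatedOrdinals named list: per scaffold, the observed
#'   regulated gene ordinals.
#' @param scaffoldGenes named integer vector: genes per scaffold.
#' @param model a [SpacingModel-class].
#' @param nPerm number of permutations (>= 100).
#' @param seed RNG seed.
#' @return list: `observed_fraction`, `p_value`, `null_fractions`.
#' @export
permutationNull <- function(regulatedOrdinals, scaffoldGenes, model,
                            nPerm = 1000, seed = 7L) {
  if (nPerm < 100) stopf("nPerm must be >= 100")
  scafs <- names(regulatedOrdinals)
  if (!all(scafs %in% names(scaffoldGenes)))
    stopf("scaffoldGenes must cover every scaffold")
  nReg <- sum(lengths(regulatedOrdinals))
  clusteredFraction <- function(ordList) {
    ng <- 0L
    for (sc in scafs) {
      ch <- chainScan(ordList[[sc]], model)
      ng <- ng + sum(lengths(ch))
    }
    ng / nReg
  }
  obs <- clusteredFraction(regulatedOrdinals)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    perm <- lapply(scafs, function(sc)
      sample.int(scaffoldGenes[[sc]], length(regulatedOrdinals[[sc]])))
    names(perm) <- scafs
    clusteredFraction(perm)
  }, numeric(1))
  list(observed_fraction = obs,
       p_value = (1 + sum(null >= obs)) / (nPerm + 1),
       null_fractions = null)
}
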