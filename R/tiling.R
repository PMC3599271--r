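#' Remove probes flagged as undetected
#'
#' Mirrors the pre-treatment step in which spots flagged by the scanner's
#' feature-extraction software are discarded before normalization.
#'
#' @param probes data.frame with a logical/0-1 `detected` column.
#' @return list with `probes` (rows with `detected == TRUE`) and
#'   `nDiscarded` (count removed).
#' @examples
#' df <- data.frame(probe_id = letters[1:4], detected = c(TRUE, FALSE, TRUE, TRUE))
#' discardFlagged(df)$nDiscarded
#' @export
discardFlagged <- function(probes) {
  if (!"detected" %in% names(probes))
    stopf("probe table lacks a 'detected' column")
  keep <- as.logical(probes$detected)
  if (!any(keep))
    warnf("all probes flagged undetected; empty table returned")
  list(probes = probes[keep, , drop = FALSE], nDiscarded = sum(!keep))
}

# locally weighted fit of M on A, evaluated at the data's A values
lowessFitAt <- function(M, A, span) {
  fit <- lowess(A, M, f = span)
  approx(fit$x, fit$y, xout = A, rule = 2, ties = mean)$y
}

#' Global Lowess normalization of two-colour log ratios
#'
#' Removes intensity-dependent trends from per-probe log2 ratios (M) by
#' subtracting a locally weighted regression of M on the mean
#' log-intensity A, fitted over all probes of the array ("global"); no
#' background subtraction is involved.
#'
#' @param M numeric vector of log2 ratios.
#' @param A numeric vector of mean log intensities (same length).
#' @param span Lowess span (fraction of points in each local window).
#' @return numeric vector of normalized M values.
#' @examples
#' A <- runif(200, 8, 16); M <- 0.5 + rnorm(200, 0, 0.1)
#' max(abs(mean(lowessNormalize(M, A)))) < 0.1
#' @export
lowessNormalize <- function(M, A, span = 0.3) {
  if (length(M) != length(A))
    stopf("M and A must have equal length")
  if (length(M) < 10)
    stopf("refusing to Lowess-normalize fewer than 10 probes (unstable fit)")
  if (any(!is.finite(M)) || any(!is.finite(A)))
    stopf("M and A must be finite")
  M - lowessFitAt(M, A, span)
}

#' Residual intensity-dependent trend after normalization
#'
#' Maximum absolute value of a Lowess fit of M on A; near zero when no
#' intensity-dependent bias remains.
#'
#' @inheritParams lowessNormalize
#' @return single numeric, `max(abs(fit))`.
#' @export
residualTrend <- function(M, A, span = 0.3) {
  max(abs(lowessFitAt(M, A, span)))
}

#' Merge a dye-swapped replicate pair probe-wise
#'
#' The swapped replicate measures the sign-inverted ratio, so the merged
#' value is `mean(M1, -M2)` per probe. Probes detected in only one
#' replicate keep that replicate's (sign-corrected) value and are flagged
#' `single_replicate`.
#'
#' @param rep1 data.frame with `probe_id`, `M` (and optionally `detected`)
#'   for the unswapped array.
#' @param rep2 same for the dye-swapped array.
#' @return data.frame: `probe_id`, `M` (merged), `detected`,
#'   `single_replicate`, `n_reps`.
#' @examples
#' r1 <- data.frame(probe_id = "p1", M = 1.8)
#' r2 <- data.frame(probe_id = "p1", M = -2.2)
#' mergeDyeSwap(r1, r2)$M  # 2.0
#' @export
mergeDyeSwap <- function(rep1, rep2) {
  for (d in list(rep1, rep2))
    if (!all(c("probe_id", "M") %in% names(d)))
      stopf("replicate tables need 'probe_id' and 'M' columns")
  d1 <- if ("detected" %in% names(rep1)) as.logical(rep1$detected)
        else rep(TRUE, nrow(rep1))
  d2 <- if ("detected" %in% names(rep2)) as.logical(rep2$detected)
        else rep(TRUE, nrow(rep2))
  ids <- union(rep1$probe_id, rep2$probe_id)
  only1 <- setdiff(rep1$probe_id, rep2$probe_id)
  only2 <- setdiff(rep2$probe_id, rep1$probe_id)
  if (length(only1) || length(only2))
    stopf("probe ids do not reconcile between replicates: %s",
          paste(head(c(only1, only2), 5), collapse = ", "))
  i1 <- match(ids, rep1$probe_id); i2 <- match(ids, rep2$probe_id)
  m1 <- ifelse(d1[i1], rep1$M[i1], NA_real_)
  m2 <- ifelse(d2[i2], -rep2$M[i2], NA_real_)
  M <- rowMeans(cbind(m1, m2), na.rm = TRUE)
  nrep <- (!is.na(m1)) + (!is.na(m2))
  M[nrep == 0L] <- NA_real_
  data.frame(probe_id = ids, M = M, detected = nrep > 0L,
             single_replicate = nrep == 1L, n_reps = nrep,
             stringsAsFactors = FALSE)
}

#' Assign probes to genes by strict strand-matched containment
#'
#' A probe is assigned to a gene iff its full interval lies within the
#' gene's span and the strands match. Probes matching no gene are
#' unassigned; a probe inside two overlapping same-strand genes is
#' assigned to both.
#'
#' @param probes data.frame with `probe_id`, `scaffold`, `start`, `end`
#'   (0-based half-open) and `strand`.
#' @param genes GRanges gene catalog (1-based, mcols `gene_id`).
#' @return data.frame `probe_id`, `gene_id` (one row per assignment).
#' @export
mapProbesToGenes <- function(probes, genes) {
  need <- c("probe_id", "scaffold", "start", "end", "strand")
  if (!all(need %in% names(probes)))
    stopf("probe table lacks columns: %s",
          paste(setdiff(need, names(probes)), collapse = ", "))
  unknown <- setdiff(unique(probes$scaffold),
                     GenomeInfoDb::seqlevels(genes))
  if (length(unknown))
    stopf("probe table names unknown scaffold(s): %s",
          paste(unknown, collapse = ", "))
  pGR <- GRanges(probes$scaffold,
                 IRanges(probes$start + 1L, probes$end),
                 strand = probes$strand)
  ov <- findOverlaps(pGR, genes, type = "within")
  data.frame(probe_id = probes$probe_id[queryHits(ov)],
             gene_id = mcols(genes)$gene_id[subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Call regulation state from a per-transcript log2 ratio
#'
#' Strict threshold rule: `up` iff ratio > threshold, `down` iff
#' ratio < -threshold, otherwise `none`; the boundary value itself is
#' `none`.
#'
#' @param log2Ratio numeric vector of per-transcript log2 ratios.
#' @param threshold positive threshold (default 1.5).
#' @return character vector in `up`, `down`, `none`.
#' @examples
#' callRegulation(c(1.6, -1.6, 1.5))  # up, down, none
#' @export
callRegulation <- function(log2Ratio, threshold = 1.5) {
  if (any(!is.finite(log2Ratio)))
    stopf("non-finite log2 ratio passed to callRegulation")
  ifelse(log2Ratio > threshold, "up",
         ifelse(log2Ratio < -threshold, "down", "none"))
}

#' Aggregate merged probe ratios to per-transcript calls
#'
#' The final ratio for each transcript is the arithmetic mean of the
#' detected probes assigned to it; transcripts with no or only one
#' detected probe are discarded.
#'
#' @param merged data.frame from [mergeDyeSwap()] (`probe_id`, `M`,
#'   `detected`).
#' @param assignment data.frame from [mapProbesToGenes()].
#' @param geneIds character vector of all gene ids in the catalog (genes
#'   with no assigned probes are reported as discarded).
#' @param threshold regulation threshold passed to [callRegulation()].
#' @return data.frame: `gene_id`, `log2_ratio`, `n_probes_detected`,
#'   `regulation` (up/down/none/discarded).
#' @export
aggregateTranscripts <- function(merged, assignment, geneIds,
                                 threshold = 1.5) {
  det <- merged[merged$detected & is.finite(merged$M), c("probe_id", "M")]
  j <- merge(assignment, det, by = "probe_id")
  n <- tapply(j$M, j$gene_id, length)
  m <- tapply(j$M, j$gene_id, mean)
  out <- data.frame(gene_id = geneIds,
                    log2_ratio = as.numeric(m[geneIds]),
                    n_probes_detected = as.integer(n[geneIds]),
                    stringsAsFactors = FALSE)
  out$n_probes_detected[is.na(out$n_probes_detected)] <- 0L
  disc <- out$n_probes_detected <= 1L
  out$regulation <- "discarded"
  out$regulation[!disc] <- callRegulation(out$log2_ratio[!disc], threshold)
  out$log2_ratio[disc] <- NA_real_
  out
}

#' Moderated t statistics via variance shrinkage
#'
#' Empirical-Bayes style moderation: per-gene sample variances are shrunk
#' toward a common prior, `sTilde2 = (d0 * s02 + d * s2) / (d0 + d)`, with
#' the prior degrees of freedom `d0` and prior variance `s02` estimated
#' from the ensemble of gene variances by method of moments (the sample
#' variances follow a scaled F distribution under the hierarchical
#' model). The moderated t is `mean / (sTilde / sqrt(n))` on `d0 + d`
#' degrees of freedom.
#'
#' @param ratios numeric matrix, genes x replicate observations.
#' @param d0,s02 optional fixed prior; when NULL both are estimated.
#' @return data.frame: `gene_id` (rownames), `mean`, `s2`, `sTilde2`,
#'   `moderated_t`, `moderated_p`, with the fitted prior in attributes
#'   `d0` and `s02`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), 100, 2)
#' fit <- moderatedStatistics(x)
#' attr(fit, "d0")
#' @export
moderatedStatistics <- function(ratios, d0 = NULL, s02 = NULL) {
  ratios <- as.matrix(ratios)
  n <- ncol(ratios)
  if (n < 2) stopf("need >= 2 replicate observations per gene")
  d <- n - 1
  mu <- rowMeans(ratios)
  s2 <- apply(ratios, 1, var)
  if (all(s2 == 0)) stopf("all gene variances are zero")
  if (is.null(d0) || is.null(s02)) {
    prior <- fitVariancePrior(s2, d)
    d0 <- prior$d0; s02 <- prior$s02
  }
  sTilde2 <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  t <- mu / sqrt(sTilde2 / n)
  df <- d0 + d
  p <- 2 * pt(-abs(t), df = df)
  out <- data.frame(mean = mu, s2 = s2, sTilde2 = sTilde2,
                    moderated_t = t, moderated_p = p)
  rownames(out) <- rownames(ratios)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

# method-of-moments fit of the scaled-F model for sample variances:
# s2 ~ s02 * F(d, d0). Matches first two moments; r <= 2/d means no
# excess dispersion and the prior dominates (d0 = Inf).
fitVariancePrior <- function(s2, d) {
  m1 <- mean(s2)
  if (m1 <= 0) stopf("mean of gene variances is not positive")
  r <- var(s2) / m1^2
  if (!is.finite(r) || r * d <= 2) {
    return(list(d0 = Inf, s02 = m1))
  }
  d0 <- (4 * r * d + 2 * d - 4) / (r * d - 2)
  if (d0 <= 4) d0 <- 4.001  # moment solution outside its domain; clamp
  list(d0 = d0, s02 = m1 * (d0 - 2) / d0)
}

#' Quantify per-transcript regulation from probe-level measurements
#'
#' Full probe-to-transcript workflow for one species: per array, discard
#' flagged probes and Lowess-normalize M on A; merge each stage's
#' dye-swapped replicate pair probe-wise; assign probes to genes by
#' strand-matched containment; average detected probes per gene; call
#' regulation against the threshold; attach moderated t statistics
#' computed from the two per-array gene-level ratios (advisory columns —
#' the gene lists of record are threshold-defined).
#'
#' @param probes probe measurement table for one species (columns as in
#'   [simulateProbeData()]).
#' @param genes GRanges gene catalog for that species.
#' @param threshold regulation threshold (|log2 ratio|).
#' @param span Lowess span.
#' @param stages stages to quantify (defaults to all present).
#' @return list with `calls` (gene_id, stage, log2_ratio,
#'   n_probes_detected, regulation, moderated_t, moderated_p) and
#'   `report` (per-array normalization report plus discard counts).
#' @export
quantifyExpression <- function(probes, genes, threshold = 1.5, span = 0.3,
                               stages = NULL) {
  if (is.null(stages)) stages <- unique(probes$stage)
  geneIds <- mcols(genes)$gene_id
  assignment <- mapProbesToGenes(
    probes[!duplicated(probes$probe_id),
           c("probe_id", "scaffold", "start", "end", "strand")], genes)

  callRows <- list(); repRows <- list()
  for (st in stages) {
    reps <- lapply(1:2, function(rp) {
      arr <- probes[probes$stage == st & probes$replicate == rp, ]
      if (!nrow(arr)) stopf("no probes for stage %s replicate %d", st, rp)
      flt <- discardFlagged(arr)
      arr <- flt$probes
      if (nrow(arr) >= 10) {
        before <- residualTrend(arr$M, arr$A, span)
        arr$M <- lowessNormalize(arr$M, arr$A, span)
        after <- residualTrend(arr$M, arr$A, span)
      } else {
        warnf("stage %s replicate %d: %d detected probes, normalization skipped",
              st, rp, nrow(arr))
        before <- after <- NA_real_
      }
      list(arr = arr, nDiscarded = flt$nDiscarded,
           trendBefore = before, trendAfter = after)
    })
    merged <- mergeDyeSwapFull(probes, st, reps)
    agg <- aggregateTranscripts(merged, assignment, geneIds, threshold)
    agg$stage <- st

    mod <- moderatedGeneStats(reps, assignment, geneIds)
    agg$moderated_t <- mod$moderated_t[match(agg$gene_id, mod$gene_id)]
    agg$moderated_p <- mod$moderated_p[match(agg$gene_id, mod$gene_id)]
    callRows[[st]] <- agg[, c("gene_id", "stage", "log2_ratio",
                              "n_probes_detected", "regulation",
                              "moderated_t", "moderated_p")]
    repRows[[st]] <- data.frame(
      stage = st, replicate = 1:2,
      n_probes_flag_discarded = vapply(reps, `[[`, 0, "nDiscarded"),
      residual_trend_before = vapply(reps, `[[`, 0, "trendBefore"),
      residual_trend_after = vapply(reps, `[[`, 0, "trendAfter"),
      stringsAsFactors = FALSE)
  }
  list(calls = rbindRows(callRows),
       report = rbindRows(repRows))
}

# dye-swap merge over the full probe universe of a stage: probes filtered
# out on one array fall back to the other array's value
mergeDyeSwapFull <- function(probes, st, reps) {
  ids <- unique(probes$probe_id[probes$stage == st])
  tab <- lapply(1:2, function(rp) {
    arr <- reps[[rp]]$arr
    i <- match(ids, arr$probe_id)
    data.frame(probe_id = ids, M = arr$M[i],
               detected = !is.na(i), stringsAsFactors = FALSE)
  })
  tab[[1]]$M[is.na(tab[[1]]$M)] <- 0  # masked by detected = FALSE
  tab[[2]]$M[is.na(tab[[2]]$M)] <- 0
  mergeDyeSwap(tab[[1]], tab[[2]])
}

# per-array gene-level ratios (sign-corrected) -> moderated statistics
moderatedGeneStats <- function(reps, assignment, geneIds) {
  perArray <- lapply(1:2, function(rp) {
    arr <- reps[[rp]]$arr
    M <- if (rp == 2L) -arr$M else arr$M
    j <- merge(assignment,
               data.frame(probe_id = arr$probe_id, M = M,
                          stringsAsFactors = FALSE),
               by = "probe_id")
    tapply(j$M, j$gene_id, mean)
  })
  mat <- cbind(as.numeric(perArray[[1]][geneIds]),
               as.numeric(perArray[[2]][geneIds]))
  rownames(mat) <- geneIds
  ok <- rowSums(is.finite(mat)) == 2L
  out <- data.frame(gene_id = geneIds, moderated_t = NA_real_,
                    moderated_p = NA_real_, stringsAsFactors = FALSE)
  if (sum(ok) >= 2 && any(apply(mat[ok, , drop = FALSE], 1, var) > 0)) {
    ms <- moderatedStatistics(mat[ok, , drop = FALSE])
    out$moderated_t[ok] <- ms$moderated_t
    out$moderated_p[ok] <- ms$moderated_p
  }
  out
}
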