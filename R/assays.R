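#' Growth inhibition of the prey in a dual-confrontation assay
#'
#' Relative reduction of the prey's radial growth versus the
#' self-confrontation control: `100 * (growth_self - growth_confronted) /
#' growth_self`. Growth against self defines zero inhibition; negative
#' values mean stimulation.
#'
#' @param growthSelf radial growth (mm) toward the self-confrontation
#'   control; must be > 0.
#' @param growthConfronted radial growth (mm) toward the confronting
#'   species.
#' @return inhibition percentage (vectorized).
#' @examples
#' inhibitionPercent(30, 30)          # 0
#' inhibitionPercent(30, 30 * 1.21)   # -21 (stimulation)
#' inhibitionPercent(30, 30 * 0.91)   # 9
#' @export
inhibitionPercent <- function(growthSelf, growthConfronted) {
  if (any(growthSelf <= 0)) stopf("growthSelf must be > 0")
  100 * (growthSelf - growthConfronted) / growthSelf
}

#' Overgrowth of the prey colony
#'
#' Advance of the antagonist's front over the prey colony as a percentage
#' of the prey colony depth (distance from the prey plug to the
#' confrontation zone), capped at 100 (full coverage).
#'
#' @param extent overgrowth extent (mm).
#' @param preyDepth prey colony depth (mm); must be > 0.
#' @return overgrowth percentage in [0, 100] (vectorized).
#' @examples
#' overgrowthPercent(43, 50)  # 86
#' @export
overgrowthPercent <- function(extent, preyDepth) {
  if (any(preyDepth <= 0)) stopf("preyDepth must be > 0")
  pmin(100, 100 * extent / preyDepth)
}

#' Amplification efficiency from a cDNA dilution series
#'
#' Least-squares fit of Ct versus log10(dilution); the efficiency is
#' `10^(-1/slope) - 1` (1 corresponds to perfect doubling, slope
#' -1/log10(2) = -3.3219).
#'
#' @param ct Ct values.
#' @param dilution matching dilution factors (e.g. 1, 0.1, 1e-2, 1e-3).
#' @return list: `efficiency`, `slope`, `r_squared`.
#' @examples
#' d <- rep(c(1, 0.1, 1e-2, 1e-3), each = 3)
#' ct <- 20 - log10(d) / log10(2)
#' efficiencyFromDilution(ct, d)$efficiency  # 1
#' @export
efficiencyFromDilution <- function(ct, dilution) {
  if (length(unique(dilution)) < 3)
    stopf("need >= 3 distinct dilution points")
  fit <- lm(ct ~ log10(dilution))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0 || abs(slope) < 0.5)
    stopf("non-amplifying dilution series (slope %.3f)", slope)
  ss <- sum((ct - mean(ct))^2)
  list(efficiency = 10^(-1 / slope) - 1,
       slope = slope,
       r_squared = if (ss > 0) 1 - sum(fit$residuals^2) / ss else NA_real_)
}

#' Relative expression by the Livak (2^-ddCt) model
#'
#' `ddCt = (Ct_target_treat - Ct_norm_treat) - (Ct_target_ctrl -
#' Ct_norm_ctrl)`; the fold change is `2^(-ddCt)`.
#'
#' @param ctTargetTreat,ctNormTreat,ctTargetCtrl,ctNormCtrl Ct values
#'   (vectorized).
#' @return fold change(s).
#' @examples
#' livakRatio(20, 18, 22, 18)  # 4
#' @export
livakRatio <- function(ctTargetTreat, ctNormTreat, ctTargetCtrl,
                       ctNormCtrl) {
  cts <- cbind(ctTargetTreat, ctNormTreat, ctTargetCtrl, ctNormCtrl)
  if (any(!is.finite(cts))) stopf("all Ct values must be finite")
  ddct <- (ctTargetTreat - ctNormTreat) - (ctTargetCtrl - ctNormCtrl)
  2^(-ddct)
}

#' Quantify a qPCR table with the Livak model
#'
#' Averages replicate Cts per (gene, condition), pairs each target with
#' the normalizer, and returns per-gene fold changes and log2 ratios.
#'
#' @param qpcr data.frame with `gene`, `role` (target/normalizer),
#'   `condition` (treatment/control), `Ct`.
#' @return data.frame: `gene`, `fold`, `log2_ratio`.
#' @export
qpcrQuantify <- function(qpcr) {
  need <- c("gene", "role", "condition", "Ct")
  if (!all(need %in% names(qpcr)))
    stopf("qPCR table lacks columns: %s",
          paste(setdiff(need, names(qpcr)), collapse = ", "))
  avg <- aggregate(Ct ~ gene + role + condition, qpcr, mean)
  norm <- avg[avg$role == "normalizer", ]
  if (!nrow(norm)) stopf("no normalizer rows in qPCR table")
  nt <- norm$Ct[norm$condition == "treatment"][1]
  nc <- norm$Ct[norm$condition == "control"][1]
  tg <- avg[avg$role == "target", ]
  genes <- unique(tg$gene)
  fold <- vapply(genes, function(g) {
    tt <- tg$Ct[tg$gene == g & tg$condition == "treatment"][1]
    tc <- tg$Ct[tg$gene == g & tg$condition == "control"][1]
    livakRatio(tt, nt, tc, nc)
  }, numeric(1))
  data.frame(gene = genes, fold = unname(fold),
             log2_ratio = log2(unname(fold)), stringsAsFactors = FALSE)
}

#' Concordance between array calls and qPCR ratios
#'
#' Per shared gene: array log2 ratio, qPCR log2 ratio and sign agreement.
#' qPCR values with |log2| at or below the threshold are zeroed (the
#' reporting convention for sub-threshold expression), and the summary
#' fraction is computed over genes whose array |log2| exceeds the
#' threshold.
#'
#' @param arrayLog2 named numeric vector of array log2 ratios.
#' @param qpcrLog2 named numeric vector of qPCR log2 ratios.
#' @param threshold regulation threshold (default 1.5).
#' @return list: `table` (gene, array_log2, qpcr_log2, qpcr_reported,
#'   concordant) and `fraction_concordant`.
#' @export
qpcrConcordance <- function(arrayLog2, qpcrLog2, threshold = 1.5) {
  genes <- intersect(names(arrayLog2), names(qpcrLog2))
  if (!length(genes)) stopf("no shared genes between array and qPCR")
  a <- arrayLog2[genes]; q <- qpcrLog2[genes]
  qr <- ifelse(abs(q) <= threshold, 0, q)
  tab <- data.frame(gene = genes, array_log2 = unname(a),
                    qpcr_log2 = unname(q), qpcr_reported = unname(qr),
                    concordant = sign(a) == sign(qr) & qr != 0,
                    stringsAsFactors = FALSE)
  sel <- abs(a) > threshold
  list(table = tab,
       fraction_concordant = if (any(sel)) mean(tab$concordant[sel])
                             else NA_real_)
}

#' Per-species confrontation-plate metrics
#'
#' @param plates data.frame with `species`, `growth_self`,
#'   `growth_confronted`, `overgrowth_extent`, `prey_colony_depth`.
#' @return data.frame: `species`, `inhibition_pct`, `overgrowth_pct`.
#' @export
plateMetrics <- function(plates) {
  need <- c("species", "growth_self", "growth_confronted",
            "overgrowth_extent", "prey_colony_depth")
  if (!all(need %in% names(plates)))
    stopf("plate table lacks columns: %s",
          paste(setdiff(need, names(plates)), collapse = ", "))
  data.frame(
    species = plates$species,
    inhibition_pct = inhibitionPercent(plates$growth_self,
                                       plates$growth_confronted),
    overgrowth_pct = overgrowthPercent(plates$overgrowth_extent,
                                       plates$prey_colony_depth),
    stringsAsFactors = FALSE)
}
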