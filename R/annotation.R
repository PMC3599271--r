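#' Classify genes by conservation from a BLAST-style hit table
#'
#' A gene is `identified` when its best hit against a non-congeneric
#' (non-Trichoderma) Sordariomycetes subject has E < 1e-100; it is
#' `orphan` when no non-congeneric Pezizomycotina hit at least as
#' significant as 1e-20 exists (genes with no hits at all are orphans);
#' everything in between is `unknown`.
#'
#' @param hits data.frame with columns `qseqid`, `evalue`,
#'   `is_trichoderma`, `is_sordariomycete`, `is_pezizomycotina`.
#' @param geneIds character vector of all genes to classify (genes absent
#'   from the hit table are classified too).
#' @param eIdentified E-value cut for `identified` (strict <).
#' @param eOrphan E-value cut defining a qualifying Pezizomycotina hit
#'   (hit qualifies when E <= eOrphan).
#' @return character vector (named by gene) in
#'   `identified`/`unknown`/`orphan`.
#' @examples
#' h <- data.frame(qseqid = "g1", evalue = 1e-120, is_trichoderma = FALSE,
#'                 is_sordariomycete = TRUE, is_pezizomycotina = TRUE)
#' classifyConservation(h, c("g1", "g2"))
#' @export
classifyConservation <- function(hits, geneIds,
                                 eIdentified = 1e-100, eOrphan = 1e-20) {
  need <- c("qseqid", "evalue", "is_trichoderma", "is_sordariomycete",
            "is_pezizomycotina")
  if (!all(need %in% names(hits)))
    stopf("hit table lacks columns: %s",
          paste(setdiff(need, names(hits)), collapse = ", "))
  if (any(hits$evalue <= 0)) stopf("E-values must be > 0")
  h <- hits[!as.logical(hits$is_trichoderma), ]
  sord <- h[as.logical(h$is_sordariomycete), ]
  pez <- h[as.logical(h$is_pezizomycotina), ]
  bestSord <- tapply(sord$evalue, sord$qseqid, min)
  bestPez <- tapply(pez$evalue, pez$qseqid, min)
  bs <- as.numeric(bestSord[geneIds])
  bp <- as.numeric(bestPez[geneIds])
  out <- rep("unknown", length(geneIds))
  out[is.na(bp) | bp > eOrphan] <- "orphan"
  out[!is.na(bs) & bs < eIdentified] <- "identified"
  setNames(out, geneIds)
}

# direction of each involved gene: the stage with the largest |log2 ratio|
# among its regulated stages decides
involvedGenes <- function(calls) {
  reg <- calls[calls$regulation %in% c("up", "down"), ]
  if (!nrow(reg))
    return(data.frame(gene_id = character(), direction = character(),
                      max_log2 = numeric(), stringsAsFactors = FALSE))
  ord <- order(reg$gene_id, -abs(reg$log2_ratio))
  reg <- reg[ord, ]
  top <- reg[!duplicated(reg$gene_id), ]
  data.frame(gene_id = top$gene_id, direction = top$regulation,
             max_log2 = top$log2_ratio, stringsAsFactors = FALSE)
}

fmtPct <- function(up, down) {
  tot <- up + down
  if (tot == 0) return("n.a.")
  sprintf("%.1f/%.1f", roundHalfUp(100 * up / tot, 1),
          roundHalfUp(100 * down / tot, 1))
}

#' Summarize regulated genes by conservation class
#'
#' Per-class counts of genes regulated in at least one stage, with
#' up/down percentages to one decimal — the shape of a per-species
#' transcript-inventory table. A gene regulated in several stages counts
#' once, with the direction of its largest |log2 ratio|.
#'
#' @param calls per-gene, per-stage calls (from [quantifyExpression()]).
#' @param classes named character vector from [classifyConservation()],
#'   covering every called gene.
#' @return data.frame: `class` (identified/unknown/orphan/all), `total`,
#'   `up`, `down`, `pct_up`, `pct_down`, `up_down` (formatted "u/d").
#' @export
conservationSummary <- function(calls, classes) {
  inv <- involvedGenes(calls)
  missing <- setdiff(inv$gene_id, names(classes))
  if (length(missing))
    stopf("genes with calls but no conservation class: %s",
          paste(head(missing, 5), collapse = ", "))
  lev <- c("identified", "unknown", "orphan")
  cls <- factor(classes[inv$gene_id], levels = lev)
  rows <- lapply(c("all", lev), function(cl) {
    sub <- if (cl == "all") inv else inv[!is.na(cls) & cls == cl, ]
    up <- sum(sub$direction == "up"); down <- sum(sub$direction == "down")
    data.frame(class = cl, total = nrow(sub), up = up, down = down,
               pct_up = if (nrow(sub)) roundHalfUp(100 * up / nrow(sub), 1)
                        else NA_real_,
               pct_down = if (nrow(sub)) roundHalfUp(100 * down / nrow(sub), 1)
                          else NA_real_,
               up_down = fmtPct(up, down),
               stringsAsFactors = FALSE)
  })
  rbindRows(rows)
}

#' Up/down ratio with the reporting conventions of functional-category tables
#'
#' One decimal, half away from zero; `"n.a."` when nothing is
#' down-regulated but something is up, or when the category is empty.
#'
#' @param up,down counts.
#' @return character scalar.
#' @examples
#' funcatRatio(13, 2)  # "6.5"
#' funcatRatio(10, 41) # "0.2"
#' funcatRatio(4, 0)   # "n.a."
#' @export
funcatRatio <- function(up, down) {
  if (up + down == 0) return("n.a.")
  if (down == 0) return("n.a.")
  format(roundHalfUp(up / down, 1), trim = TRUE)
}

#' Summarize regulation by FunCat category
#'
#' Per functional category: number of involved genes (regulated in at
#' least one stage, counted once with the direction of the largest
#' |log2 ratio|), up and down counts, and the up/down ratio with
#' one-decimal reporting.
#'
#' @param calls per-gene, per-stage calls for one species.
#' @param funcat data.frame with `gene_id`, `funcat_number`, `label`.
#' @return data.frame: `funcat_number`, `label`, `total`, `up`, `down`,
#'   `ratio` (character, "n.a." allowed).
#' @export
funcatSummary <- function(calls, funcat) {
  inv <- involvedGenes(calls)
  cats <- unique(funcat[, c("funcat_number", "label")])
  rows <- lapply(seq_len(nrow(cats)), function(i) {
    gids <- funcat$gene_id[funcat$funcat_number == cats$funcat_number[i] &
                             funcat$label == cats$label[i]]
    sub <- inv[inv$gene_id %in% gids, ]
    up <- sum(sub$direction == "up"); down <- sum(sub$direction == "down")
    data.frame(funcat_number = cats$funcat_number[i], label = cats$label[i],
               total = nrow(sub), up = up, down = down,
               ratio = funcatRatio(up, down), stringsAsFactors = FALSE)
  })
  rbindRows(rows)
}
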