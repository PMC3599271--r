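#' Cross-species Venn regions of regulated orthogroups
#'
#' Places each orthogroup in a Venn region according to which species
#' have a regulated member (optionally restricted to one direction).
#' Regulated genes belonging to no orthogroup count as species-specific
#' singletons in their own species' region. The counting unit is the
#' orthogroup, so a gene shared by all species counts once.
#'
#' @param involved data.frame with `species`, `gene_id` and `direction`
#'   ("up"/"down") for every gene regulated in at least one stage.
#' @param orthogroups data.frame with `group_id`, `species`, `gene_id`.
#' @param species character vector fixing species order for region names.
#' @param direction `"any"`, `"up"` or `"down"`: with a direction filter,
#'   only members regulated in that direction place a species in the
#'   region.
#' @return list with `counts` (named integer vector over all non-empty
#'   species subsets, names like `"Ta"`, `"Ta&Tv"`), and `assignment`
#'   (data.frame `unit_id`, `type` = group/singleton, `region`).
#' @export
orthologyVenn <- function(involved, orthogroups, species,
                          direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  bad <- setdiff(involved$species, species)
  if (length(bad))
    stopf("involved table names unknown species: %s",
          paste(bad, collapse = ", "))
  sel <- involved
  if (direction != "any") sel <- sel[sel$direction == direction, ]
  key <- paste(sel$species, sel$gene_id)

  og <- orthogroups[paste(orthogroups$species, orthogroups$gene_id) %in% key, ]
  regionOf <- function(spp) paste(species[species %in% spp], collapse = "&")
  groupRegion <- tapply(og$species, og$group_id,
                        function(s) regionOf(unique(s)))

  inGroup <- paste(orthogroups$species, orthogroups$gene_id)
  singles <- sel[!(paste(sel$species, sel$gene_id) %in% inGroup), ]

  assignment <- rbind(
    if (length(groupRegion))
      data.frame(unit_id = names(groupRegion), type = "group",
                 region = as.character(groupRegion),
                 stringsAsFactors = FALSE),
    if (nrow(singles))
      data.frame(unit_id = singles$gene_id, type = "singleton",
                 region = singles$species, stringsAsFactors = FALSE))

  regions <- allRegions(species)
  counts <- setNames(integer(length(regions)), regions)
  if (!is.null(assignment) && nrow(assignment)) {
    tb <- table(assignment$region)
    counts[names(tb)] <- as.integer(tb)
  }
  list(counts = counts,
       assignment = if (is.null(assignment))
         data.frame(unit_id = character(), type = character(),
                    region = character(), stringsAsFactors = FALSE)
       else assignment)
}

# all non-empty subsets of the species vector, in subset-size order
allRegions <- function(species) {
  n <- length(species)
  subsets <- unlist(lapply(seq_len(n), function(k)
    utils::combn(species, k, FUN = paste, collapse = "&",
                 simplify = FALSE)), use.names = FALSE)
  subsets
}

#' Per-region gene lists with conservation classes
#'
#' Expands a Venn assignment back to member genes, attaching each gene's
#' conservation class (and FunCat label when available); empty regions
#' are present with zero rows in the `regions` attribute.
#'
#' @param venn result of [orthologyVenn()].
#' @param orthogroups data.frame `group_id`, `species`, `gene_id`.
#' @param involved the involved-gene table given to [orthologyVenn()].
#' @param classes named vector of conservation classes (per
#'   species-qualified gene id, or plain gene id).
#' @return data.frame: `region`, `unit_id`, `species`, `gene_id`, `class`.
#' @export
sharedSetReport <- function(venn, orthogroups, involved, classes = NULL) {
  asg <- venn$assignment
  rows <- lapply(seq_len(nrow(asg)), function(i) {
    if (asg$type[i] == "group") {
      mem <- orthogroups[orthogroups$group_id == asg$unit_id[i], ]
      mem <- mem[paste(mem$species, mem$gene_id) %in%
                   paste(involved$species, involved$gene_id), ]
      data.frame(region = asg$region[i], unit_id = asg$unit_id[i],
                 species = mem$species, gene_id = mem$gene_id,
                 stringsAsFactors = FALSE)
    } else {
      sp <- involved$species[involved$gene_id == asg$unit_id[i]][1]
      data.frame(region = asg$region[i], unit_id = asg$unit_id[i],
                 species = sp, gene_id = asg$unit_id[i],
                 stringsAsFactors = FALSE)
    }
  })
  out <- rbindRows(rows)
  if (is.null(out))
    out <- data.frame(region = character(), unit_id = character(),
                      species = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  out$class <- if (!is.null(classes)) unname(classes[out$gene_id])
               else NA_character_
  attr(out, "regions") <- names(venn$counts)
  out
}

#' Stage-wise expression kinetics with ANOVA and Tukey HSD
#'
#' For the genes involved in the interaction (regulated in at least one
#' stage), summarizes the per-stage distribution of log2 ratios: mean,
#' 0.95 t-interval half-width and n per stage; one-way ANOVA for a stage
#' effect; and Tukey honest-significant-difference adjusted p-values for
#' the stage pairs.
#'
#' @param calls per-gene, per-stage calls for one species.
#' @param conf confidence level for the interval.
#' @return list: `profiles` (stage, n, mean, ci_half), `anova`
#'   (F, p, df1, df2), `tukey` (pair, diff, p_adj).
#' @export
stageKinetics <- function(calls, conf = 0.95) {
  inv <- involvedGenes(calls)
  dat <- calls[calls$gene_id %in% inv$gene_id &
                 calls$regulation != "discarded" &
                 is.finite(calls$log2_ratio), ]
  cnt <- table(dat$stage)
  drop <- names(cnt)[cnt < 2]
  if (length(drop)) {
    warnf("excluding stage(s) with n < 2: %s", paste(drop, collapse = ", "))
    dat <- dat[!dat$stage %in% drop, ]
  }
  if (length(unique(dat$stage)) < 2)
    stopf("need >= 2 stages with n >= 2 for kinetics")
  profiles <- do.call(rbind, lapply(split(dat, dat$stage), function(d) {
    n <- nrow(d); m <- mean(d$log2_ratio); s <- sd(d$log2_ratio)
    data.frame(stage = d$stage[1], n = n, mean = m,
               ci_half = qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n),
               stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL
  dat$stage <- factor(dat$stage)
  fit <- aov(log2_ratio ~ stage, data = dat)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, conf.level = conf)$stage
  list(profiles = profiles,
       anova = data.frame(F = an[1, "F value"], p = an[1, "Pr(>F)"],
                          df1 = an[1, "Df"], df2 = an[2, "Df"]),
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL,
                          stringsAsFactors = FALSE))
}
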