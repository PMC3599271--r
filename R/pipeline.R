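#' Run the full confrontation-transcriptomics pipeline on synthetic data
#'
#' Simulates a confrontation experiment, writes every input to `outDir`,
#' reads them back through the package's parsers, and executes the
#' analysis end to end: per-species probe-to-transcript quantification
#' and regulation calls, conservation-class and FunCat summaries,
#' cross-species orthogroup Venn comparison, stage kinetics, genomic
#' cluster-density scan with permutation null, and plate/qPCR assay
#' metrics. All per-species tables are written as TSV and the run report
#' as JSON; the report is returned invisibly.
#'
#' @param config a [SimulationConfig-class]; its seed fixes every source
#'   of randomness, so two runs with the same config are identical.
#' @param outDir output directory.
#' @param threshold regulation threshold (|log2 ratio|).
#' @param span Lowess span.
#' @param spacingRound rounding mode for the expected batch size.
#' @param endWindow scaffold-end window (fraction of scaffold genes).
#' @param nPerm permutations for the cluster-scan null.
#' @param direction direction filter for the Venn comparison.
#' @return the run report (a nested list), invisibly.
#' @export
runPipeline <- function(config = simulationConfig(), outDir,
                        threshold = 1.5, span = 0.3,
                        spacingRound = "round", endWindow = 0.1,
                        nPerm = 200, direction = "any") {
  t0 <- Sys.time()
  sim <- simulateConfrontation(config)
  paths <- writeSimulation(sim, outDir)

  species <- config@speciesNames
  perSpecies <- list()
  involvedRows <- list()
  classesAll <- character()

  for (sp in species) {
    genes <- readGeneCatalog(paths[[sprintf("genes_%s", sp)]])
    probes <- readProbeTable(paths[[sprintf("measurements_%s", sp)]],
                             paths[[sprintf("probedefs_%s", sp)]])
    q <- quantifyExpression(probes, genes, threshold = threshold,
                            span = span, stages = STAGES)
    writeTsv(q$calls, file.path(outDir, sprintf("calls_%s.tsv", sp)))

    hits <- readTsv(file.path(outDir, "hits.tsv"))
    cls <- classifyConservation(hits[hits$species == sp, ],
                                mcols(genes)$gene_id)
    classesAll <- c(classesAll, cls)
    tab1 <- conservationSummary(q$calls, cls)
    writeTsv(tab1, file.path(outDir, sprintf("class_summary_%s.tsv", sp)))

    funcat <- readTsv(file.path(outDir, "funcat.tsv"))
    tab2 <- funcatSummary(q$calls, funcat[funcat$species == sp, ])
    writeTsv(tab2, file.path(outDir, sprintf("funcat_summary_%s.tsv", sp)))

    inv <- involvedGenes(q$calls)
    involvedRows[[sp]] <- if (nrow(inv))
      cbind(data.frame(species = sp, stringsAsFactors = FALSE), inv)

    model <- expectedSpacing(length(genes), max(1L, nrow(inv)),
                             roundMode = spacingRound)
    clusters <- scanGenomeClusters(genes, inv$gene_id, model, endWindow)
    writeTsv(clusters[, c("scaffold", "area", "density", "fold", "at_end")],
             file.path(outDir, sprintf("clusters_%s.tsv", sp)))
    csum <- clusterSummary(clusters, max(1L, nrow(inv)))

    gdf <- data.frame(scaffold = as.character(seqnames(genes)),
                      gene_id = mcols(genes)$gene_id,
                      ordinal = mcols(genes)$ordinal,
                      stringsAsFactors = FALSE)
    regOrd <- split(gdf$ordinal[gdf$gene_id %in% inv$gene_id],
                    gdf$scaffold[gdf$gene_id %in% inv$gene_id])
    scafGenes <- table(gdf$scaffold)
    perm <- if (length(regOrd) && nrow(inv) > 0)
      permutationNull(regOrd,
                      setNames(as.integer(scafGenes), names(scafGenes)),
                      model, nPerm = nPerm, seed = config@seed + 3L)
    else list(observed_fraction = 0, p_value = 1)

    kin <- tryCatch(suppressWarnings(stageKinetics(q$calls)),
                    error = function(e) NULL)

    perSpecies[[sp]] <- list(
      n_genes = length(genes),
      n_discarded = sum(q$calls$regulation == "discarded") / length(STAGES),
      regulated = lapply(setNames(STAGES, STAGES), function(st)
        list(up = sum(q$calls$stage == st & q$calls$regulation == "up"),
             down = sum(q$calls$stage == st & q$calls$regulation == "down"))),
      n_involved = nrow(inv),
      expected_batch_size = model@S,
      clusters = csum,
      cluster_permutation_p = perm$p_value,
      stage_anova_p = if (!is.null(kin)) kin$anova$p else NA,
      normalization = q$report)
  }

  involved <- rbindRows(involvedRows)
  venn <- orthologyVenn(involved, sim@orthogroups, species, direction)
  shared <- sharedSetReport(venn, sim@orthogroups, involved,
                            setNames(classesAll, names(classesAll)))
  writeTsv(shared, file.path(outDir, "venn_regions.tsv"))

  pm <- plateMetrics(readTsv(file.path(outDir, "plates.tsv")))
  writeTsv(pm, file.path(outDir, "plate_metrics.tsv"))
  qq <- qpcrQuantify(readTsv(file.path(outDir, "qpcr.tsv")))
  writeTsv(qq, file.path(outDir, "qpcr_ratios.tsv"))
  dil <- readTsv(file.path(outDir, "dilution.tsv"))
  eff <- efficiencyFromDilution(dil$Ct, dil$dilution)

  report <- list(
    package = "mycotrans",
    version = as.character(utils::packageVersion("mycotrans")),
    seed = config@seed,
    threshold = threshold,
    species = perSpecies,
    venn = as.list(venn$counts),
    assays = list(
      plates = setNames(as.list(pm$inhibition_pct), pm$species),
      overgrowth = setNames(as.list(pm$overgrowth_pct), pm$species),
      qpcr_log2 = setNames(as.list(qq$log2_ratio), qq$gene),
      efficiency = eff$efficiency),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  writeReport(report, file.path(outDir, "report.json"))
  invisible(report)
}

#' Write a run report as JSON
#'
#' @param report nested list (from [runPipeline()]).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeReport <- function(report, path) {
  report$elapsed_s <- NULL  # keep reports byte-comparable across reruns
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
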