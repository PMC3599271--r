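#' @importFrom rtracklayer import export
NULL

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, required = NULL) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss))
      stopf("%s lacks required column(s): %s", basename(path),
            paste(miss, collapse = ", "))
  }
  df
}

#' Write a gene catalog as GFF3
#'
#' One `gene` feature per gene with an `ID` attribute; 1-based inclusive
#' coordinates.
#'
#' @param genes GRanges with mcols `gene_id`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGeneCatalog <- function(genes, path) {
  gr <- genes
  mcols(gr) <- NULL
  mcols(gr)$type <- "gene"
  mcols(gr)$ID <- mcols(genes)$gene_id
  export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 gene catalog
#'
#' Keeps `gene` features, takes the `ID` attribute as the gene id, and
#' assigns 1-based ordinals per scaffold by start-coordinate order.
#'
#' @param path GFF3 file.
#' @return GRanges with mcols `gene_id`, `ordinal`.
#' @export
readGeneCatalog <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  gr <- tryCatch(import(path, format = "gff3"),
                 error = function(e) stopf("corrupt GFF3 %s: %s",
                                           basename(path),
                                           conditionMessage(e)))
  if ("type" %in% names(mcols(gr)))
    gr <- gr[as.character(mcols(gr)$type) == "gene"]
  if (!length(gr)) stopf("no gene features in %s", basename(path))
  ids <- mcols(gr)$ID
  if (is.null(ids) || anyNA(ids))
    stopf("gene features in %s lack ID attributes", basename(path))
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr))
  seqlengths(out) <- seqlengths(gr)
  mcols(out)$gene_id <- as.character(ids)
  ord <- order(as.character(seqnames(out)), start(out))
  out <- out[ord]
  mcols(out)$ordinal <- stats::ave(seq_along(out),
                                   as.character(seqnames(out)),
                                   FUN = seq_along)
  out
}

#' Write all simulated inputs of a confrontation experiment to disk
#'
#' Emits, per species, the gene catalog (GFF3), probe definitions
#' (BED-like TSV, 0-based half-open) and probe measurements (TSV), plus
#' the orthogroup, conservation-hit, FunCat, plate, qPCR and dilution
#' tables, and the ground truth as separate `truth_*` files that no
#' pipeline stage reads.
#'
#' @param sim a [ConfrontationSim-class].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (sp in names(sim@catalogs)) {
    p <- file.path(dir, sprintf("genes_%s.gff3", sp))
    writeGeneCatalog(sim@catalogs[[sp]], p)
    paths[sprintf("genes_%s", sp)] <- p
    pr <- sim@probes[sim@probes$species == sp, ]
    defs <- unique(pr[, c("scaffold", "start", "end", "probe_id", "strand")])
    paths[sprintf("probedefs_%s", sp)] <-
      writeTsv(defs, file.path(dir, sprintf("probedefs_%s.tsv", sp)))
    meas <- pr[, c("probe_id", "stage", "replicate", "dye_swapped",
                   "A", "M", "detected")]
    meas$detected <- as.integer(meas$detected)
    meas$dye_swapped <- as.integer(meas$dye_swapped)
    paths[sprintf("measurements_%s", sp)] <-
      writeTsv(meas, file.path(dir, sprintf("measurements_%s.tsv", sp)))
  }
  paths["orthogroups"] <- writeTsv(sim@orthogroups,
                                   file.path(dir, "orthogroups.tsv"))
  paths["hits"] <- writeTsv(sim@hits, file.path(dir, "hits.tsv"))
  paths["funcat"] <- writeTsv(sim@funcat, file.path(dir, "funcat.tsv"))
  paths["plates"] <- writeTsv(sim@assays$plates,
                              file.path(dir, "plates.tsv"))
  paths["qpcr"] <- writeTsv(sim@assays$qpcr, file.path(dir, "qpcr.tsv"))
  paths["dilution"] <- writeTsv(sim@assays$dilution,
                                file.path(dir, "dilution.tsv"))
  paths["truth_regulated"] <- writeTsv(sim@truth$regulated,
                                       file.path(dir, "truth_regulated.tsv"))
  paths["truth_clusters"] <- writeTsv(sim@truth$clusters,
                                      file.path(dir, "truth_clusters.tsv"))
  invisible(paths)
}

#' Read a probe measurement table joined to its probe definitions
#'
#' @param measurementsPath TSV with `probe_id`, `stage`, `replicate`,
#'   `dye_swapped`, `A`, `M`, `detected`.
#' @param defsPath BED-like TSV with `scaffold`, `start`, `end`,
#'   `probe_id`, `strand`.
#' @return data.frame in the in-memory probe-table layout.
#' @export
readProbeTable <- function(measurementsPath, defsPath) {
  meas <- readTsv(measurementsPath,
                  c("probe_id", "stage", "replicate", "A", "M", "detected"))
  defs <- readTsv(defsPath,
                  c("scaffold", "start", "end", "probe_id", "strand"))
  out <- merge(meas, defs, by = "probe_id")
  out$detected <- as.logical(out$detected)
  if ("dye_swapped" %in% names(out))
    out$dye_swapped <- as.logical(out$dye_swapped)
  out
}
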