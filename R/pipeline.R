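#' Pipeline run configuration
#'
#' Collects input paths and analysis parameters for the orchestrated runs
#' ([runIhsScan()], [runFstScan()], [runFull()], [runSimulate()]). All
#' parameters default to the package-wide values; the configuration is
#' serialized into every run's manifest.
#'
#' @param vcf path to the phased VCF.
#' @param popMap path to the sample-to-population TSV.
#' @param ancestral path to the ancestral-allele TSV.
#' @param genes optional path to a gene BED/GFF3.
#' @param trios optional path to a trio TSV (Mendelian QC).
#' @param outDir output directory.
#' @param windowSize analysis window width, bp (default 500 kb).
#' @param decayFloor EHH decay/integration floor (default 0.05).
#' @param maxGap maximum inter-marker gap, bp (default 200 kb).
#' @param mafMin core minor-allele-frequency floor (default 0.05).
#' @param minCallRate optional QC call-rate threshold (e.g. 0.90).
#' @param fdrMethod `"storey_lambda"` or `"bh"`.
#' @param fdrLambda Storey tail cutoff (default 0.75).
#' @param qThreshold window significance level on q (default 0.05).
#' @param topFraction FST top fraction (default 0.001).
#' @param seed seed for any stochastic stage (default 1).
#' @return list of class `"runConfig"`.
#' @export
runConfig <- function(vcf = NULL, popMap = NULL, ancestral = NULL,
                      genes = NULL, trios = NULL, outDir = "haploSweep_out",
                      windowSize = 5e5, decayFloor = 0.05, maxGap = 2e5,
                      mafMin = 0.05, minCallRate = NULL,
                      fdrMethod = c("storey_lambda", "bh"), fdrLambda = 0.75,
                      qThreshold = 0.05, topFraction = 0.001, seed = 1L) {
  fdrMethod <- match.arg(fdrMethod)
  stopifnot(windowSize > 0, decayFloor > 0, decayFloor < 1,
            mafMin >= 0, mafMin < 0.5, qThreshold > 0, qThreshold <= 1,
            topFraction > 0, topFraction <= 1)
  structure(list(vcf = vcf, popMap = popMap, ancestral = ancestral,
                 genes = genes, trios = trios, outDir = outDir,
                 windowSize = windowSize, decayFloor = decayFloor,
                 maxGap = maxGap, mafMin = mafMin, minCallRate = minCallRate,
                 fdrMethod = fdrMethod, fdrLambda = fdrLambda,
                 qThreshold = qThreshold, topFraction = topFraction,
                 seed = as.integer(seed)),
            class = "runConfig")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeManifest <- function(cfg, stage, outputs) {
  inputs <- Filter(Negate(is.null),
                   cfg[c("vcf", "popMap", "ancestral", "genes", "trios")])
  manifest <- list(
    package = "haploSweep",
    version = as.character(utils::packageVersion("haploSweep")),
    stage = stage,
    parameters = cfg[setdiff(names(cfg),
                             c("vcf", "popMap", "ancestral", "genes", "trios"))],
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    outputs = as.list(outputs))
  path <- file.path(cfg$outDir, sprintf("manifest_%s.json", stage))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

loadPanel <- function(cfg, needAncestral = TRUE) {
  hs <- readPhasedVcf(cfg$vcf, cfg$popMap)
  qc <- applyQc(hs, minCallRate = cfg$minCallRate, dropMonomorphic = TRUE,
                trios = cfg$trios)
  report <- qc$report
  hs <- qc$haplotypes
  if (needAncestral) {
    pol <- polarize(hs, cfg$ancestral)
    report$n_removed_unpolarized <- pol$report$n_removed_unpolarized
    report$n_retained <- pol$report$n_retained
    hs <- pol$haplotypes
  }
  list(haplotypes = hs, report = report)
}

#' Run the within-population iHS scan
#'
#' Ingests, QCs and polarizes the panel, then per population: iHS scan,
#' frequency-binned standardization, per-SNP p-values, 500-kb window
#' scores, FDR and significance calls. Writes per-SNP and window TSVs, a
#' significant-window BED per population, the cross-population overlap
#' matrix, and a JSON manifest. Reruns with an unchanged configuration are
#' byte-identical.
#'
#' @param cfg a [runConfig()] with `vcf`, `popMap` and `ancestral` set.
#' @return list with `calls` (per-population called window data.frames),
#'   `overlap` ([crossPopulationOverlap()] result), `qc` (the QC report)
#'   and `files`.
#' @export
runIhsScan <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  panel <- loadPanel(cfg)
  hs <- panel$haplotypes
  pops <- unique(populations(hs))
  files <- character(0)
  calls <- list()
  for (pp in pops) {
    sub <- hs[rep(populations(hs) == pp, each = 2L), ]
    rec <- ihsScan(sub, decayFloor = cfg$decayFloor, maxGap = cfg$maxGap,
                   mafMin = cfg$mafMin)
    std <- standardizeIhs(rec)
    rec <- ihsPvalues(std$records)
    files[sprintf("ihs_%s", pp)] <-
      writeTsv(rec, file.path(cfg$outDir, sprintf("ihs_%s.tsv", pp)))
    sc <- scoreWindows(rec, windowSize = cfg$windowSize)
    sc <- callRegions(sc, qThreshold = cfg$qThreshold, method = cfg$fdrMethod,
                      lambda = cfg$fdrLambda)
    calls[[pp]] <- sc
    files[sprintf("windows_%s", pp)] <-
      writeTsv(sc, file.path(cfg$outDir, sprintf("windows_%s.tsv", pp)))
    files[sprintf("bed_%s", pp)] <- writeSignificantBed(
      sc, file.path(cfg$outDir, sprintf("significant_%s.bed", pp)))
  }
  overlap <- NULL
  if (length(pops) >= 2) {
    tiled <- lapply(calls, padToCommonTiling, calls = calls)
    overlap <- crossPopulationOverlap(tiled)
    files["overlap"] <- writeTsv(
      as.data.frame(overlap$counts),
      file.path(cfg$outDir, "overlap_matrix.tsv"))
  }
  files["qc"] <- writeTsv(as.data.frame(unclass(panel$report)),
                          file.path(cfg$outDir, "qc_report.tsv"))
  files["manifest"] <- writeManifest(cfg, "ihs", files)
  list(calls = calls, overlap = overlap, qc = panel$report, files = files)
}

# Windows emitted per population can differ (a window with no valid record
# in one breed is dropped there); pad every call set onto the union tiling
# with empty windows marked non-significant so overlap counting sees one
# tiling.
padToCommonTiling <- function(d, calls) {
  all <- unique(do.call(rbind, lapply(calls, function(x)
    x[, c("chrom", "start", "end")])))
  key <- paste(all$chrom, all$start)
  have <- paste(d$chrom, d$start)
  miss <- all[!key %in% have, , drop = FALSE]
  if (nrow(miss)) {
    pad <- data.frame(chrom = miss$chrom, start = miss$start, end = miss$end,
                      n_snps = 0L, mean_abs_ihs = NA_real_,
                      p_two_sided = NA_real_, q = NA_real_,
                      significant = FALSE, stringsAsFactors = FALSE)
    d <- rbind(d[, names(pad)], pad)
  }
  d[order(d$chrom, d$start), , drop = FALSE]
}

#' Run the across-population global FST scan
#'
#' Ingests and QCs the panel (polarization is not required for FST), then
#' computes per-SNP global Weir-Cockerham FST, empirical p-values and the
#' top-fraction calls, and writes the per-SNP TSV, top-SNP BED, summary
#' JSON and manifest.
#'
#' @param cfg a [runConfig()] with `vcf` and `popMap` set.
#' @return list with `records`, `summary` ([summarizeFst()]) and `files`.
#' @export
runFstScan <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  panel <- loadPanel(cfg, needAncestral = FALSE)
  rec <- wcFst(panel$haplotypes)
  rec <- empiricalPvalues(rec)
  rec <- callTopFraction(rec, fraction = cfg$topFraction)
  files <- c(
    fst = writeTsv(rec, file.path(cfg$outDir, "fst.tsv")),
    fst_bed = writeTopFstBed(rec, file.path(cfg$outDir, "fst_top.bed")))
  smry <- summarizeFst(rec)
  files["fst_summary"] <- file.path(cfg$outDir, "fst_summary.json")
  jsonlite::write_json(smry, files["fst_summary"], auto_unbox = TRUE,
                       digits = NA)
  files["manifest"] <- writeManifest(cfg, "fst", files)
  list(records = rec, summary = smry, files = files)
}

#' Run both scans plus gene annotation and method intersection
#'
#' Runs [runIhsScan()] and [runFstScan()], then (when a gene catalogue is
#' configured) maps each population's significant windows and the top-FST
#' SNPs to genes and intersects the two gene sets per population, mirroring
#' the candidate-gene tables a two-pronged scan reports.
#'
#' @param cfg a [runConfig()].
#' @return list with `ihs`, `fst`, `annotation` (per-population
#'   [intersectMethods()] results plus a TSV), and `files`.
#' @export
runFull <- function(cfg) {
  ihs <- runIhsScan(cfg)
  fst <- runFstScan(cfg)
  files <- c(ihs$files, fst$files)
  annotation <- NULL
  if (!is.null(cfg$genes)) {
    genes <- readGenes(cfg$genes)
    fstGenes <- genesWithTopSnps(fst$records, genes)$gene_id
    annotation <- lapply(names(ihs$calls), function(pp) {
      intersectMethods(genesInWindows(ihs$calls[[pp]], genes), fstGenes, pp)
    })
    names(annotation) <- names(ihs$calls)
    tab <- do.call(rbind, lapply(annotation, function(x)
      data.frame(population = x$population,
                 n_ihs_genes = length(x$genes_ihs),
                 n_fst_genes = length(x$genes_fst),
                 n_both = length(x$genes_both),
                 genes_both = paste(x$genes_both, collapse = ","),
                 stringsAsFactors = FALSE)))
    files["genes"] <- writeTsv(tab, file.path(cfg$outDir, "method_intersection.tsv"))
  }
  files["manifest_full"] <- writeManifest(cfg, "full", files)
  list(ihs = ihs, fst = fst, annotation = annotation, files = files)
}

#' Simulate a panel bundle to disk
#'
#' Convenience wrapper: build a synthetic panel from a [simConfig()] (with
#' optional sweep and F-model divergence), plus a gene catalogue and
#' pedigree, and write the full plain-text bundle with [writePanel()].
#'
#' @param simCfg a [simConfig()].
#' @param dir output directory.
#' @param model `"neutral"` (mosaic background; sweep injected when
#'   configured) or `"diverged"` (F-model frequencies).
#' @param nGenes genes in the catalogue (default 100; 0 to skip).
#' @return named file vector, invisibly (as [writePanel()]).
#' @export
runSimulate <- function(simCfg, dir, model = c("neutral", "diverged"),
                        nGenes = 100L) {
  model <- match.arg(model)
  panel <- if (model == "diverged") divergePopulations(simCfg)
           else simulateNeutral(simCfg)
  if (model == "neutral" && !is.null(simCfg$sweep))
    panel <- injectSweep(panel, simCfg)
  genes <- if (nGenes > 0) makeGeneCatalogue(simCfg, nGenes = nGenes) else NULL
  ped <- makePedigree(simCfg)$pedigree
  writePanel(panel, dir, genes = genes, pedigree = ped)
}
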