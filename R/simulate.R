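#' Simulation configuration
#'
#' Bundles the parameters of the seeded synthetic-data generators. Defaults
#' emulate a multi-breed SNP-array panel at desk scale: 7 populations, a
#' mean adjacent-SNP spacing of 3,560 bp, a recombination-mosaic background
#' whose segments average 1 Mb (motivating 500-kb analysis windows), and an
#' among-population differentiation level F = 0.10 (the "moderate" band).
#'
#' @param seed integer seed; mandatory, every generator is a pure function
#'   of the configuration.
#' @param nPopulations number of populations (default 7).
#' @param haplotypesPerPopulation haplotypes per population (default 100,
#'   i.e. 50 diploid samples); must be even.
#' @param nChromosomes number of chromosomes (default 1).
#' @param chromLength chromosome length in bp (default 10 Mb).
#' @param snpSpacing mean adjacent-SNP distance in bp (default 3560).
#' @param founderHaplotypes number of founder haplotypes the mosaics copy
#'   from (default 20).
#' @param mosaicSwitchRate per-bp probability of switching copy template
#'   (default 1e-6, mean segment 1 Mb).
#' @param divergenceF target F-model differentiation for
#'   [divergePopulations()] (default 0.10).
#' @param ancestralMisassignment probability that a locus's recorded
#'   ancestral allele is deliberately wrong (default 0; a knob for testing
#'   polarization robustness).
#' @param sweep optional list for [injectSweep()]: `chrom`, `position` (bp),
#'   `frequency` (present-day derived frequency in (0,1)), `width` (bp of
#'   shared carrier haplotype; default 1 Mb).
#' @return list of class `"simConfig"`.
#' @export
simConfig <- function(seed, nPopulations = 7L, haplotypesPerPopulation = 100L,
                      nChromosomes = 1L, chromLength = 1e7, snpSpacing = 3560,
                      founderHaplotypes = 20L, mosaicSwitchRate = 1e-6,
                      divergenceF = 0.10, ancestralMisassignment = 0,
                      sweep = NULL) {
  stopifnot(!missing(seed), length(seed) == 1L, is.finite(seed),
            haplotypesPerPopulation %% 2L == 0L,
            mosaicSwitchRate >= 0, mosaicSwitchRate <= 1,
            divergenceF > 0, divergenceF < 1,
            ancestralMisassignment >= 0, ancestralMisassignment <= 1)
  if (!is.null(sweep)) {
    stopifnot(is.list(sweep), !is.null(sweep$position), !is.null(sweep$frequency),
              sweep$frequency > 0, sweep$frequency < 1)
    if (is.null(sweep$chrom)) sweep$chrom <- "1"
    if (is.null(sweep$width)) sweep$width <- 1e6
  }
  structure(list(seed = as.integer(seed), nPopulations = as.integer(nPopulations),
                 haplotypesPerPopulation = as.integer(haplotypesPerPopulation),
                 nChromosomes = as.integer(nChromosomes),
                 chromLength = chromLength, snpSpacing = snpSpacing,
                 founderHaplotypes = as.integer(founderHaplotypes),
                 mosaicSwitchRate = mosaicSwitchRate,
                 divergenceF = divergenceF,
                 ancestralMisassignment = ancestralMisassignment,
                 sweep = sweep),
            class = "simConfig")
}

# Internal: shared panel skeleton. Draws variant positions (exponential
# gaps with the configured mean), founder frequencies ~ U(0.05, 0.95),
# founder haplotypes, and the ancestral-allele assignment
# (founder-majority, optionally mis-assigned). Assumes the RNG seed is set.
simPanelSkeleton <- function(cfg) {
  chroms <- as.character(seq_len(cfg$nChromosomes))
  posList <- lapply(chroms, function(ch) {
    gaps <- stats::rexp(ceiling(cfg$chromLength / cfg$snpSpacing * 1.5),
                        rate = 1 / cfg$snpSpacing)
    p <- cumsum(1 + round(gaps))
    p <- p[p <= cfg$chromLength]
    if (length(p) < 2) stop("chromLength too short for the SNP spacing")
    p
  })
  m <- sum(lengths(posList))
  chrom <- rep(chroms, lengths(posList))
  pos <- unlist(posList, use.names = FALSE)
  u <- stats::runif(m, 0.05, 0.95)      # founder allele-1 frequency per locus
  founders <- matrix(stats::rbinom(cfg$founderHaplotypes * m, 1L,
                                   rep(u, each = cfg$founderHaplotypes)),
                     nrow = cfg$founderHaplotypes)
  # ancestral = founder-majority allele (ties -> allele 0); 1 codes ALT
  ancAllele <- ifelse(colMeans(founders) > 0.5, 1L, 0L)
  if (cfg$ancestralMisassignment > 0) {
    flip <- stats::runif(m) < cfg$ancestralMisassignment
    ancAllele[flip] <- 1L - ancAllele[flip]
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  list(chrom = chrom, pos = pos, u = u, founders = founders,
       ancAllele = ancAllele, ref = ref, alt = unname(alt))
}

# Internal: draw one mosaic haplotype over the founders (geometric segment
# lengths from the per-bp switch rate; template resampled at each switch).
mosaicRows <- function(nHap, skel, cfg) {
  m <- length(skel$pos)
  gapBp <- ifelse(c(TRUE, skel$chrom[-1] != skel$chrom[-m]),
                  Inf, c(0, diff(skel$pos)))       # chromosome break = new draw
  pSwitch <- ifelse(is.infinite(gapBp), 1, 1 - exp(-cfg$mosaicSwitchRate * gapBp))
  out <- matrix(0L, nHap, m)
  for (i in seq_len(nHap)) {
    switches <- stats::runif(m) < pSwitch
    seg <- cumsum(switches) + 1L
    tmpl <- sample.int(cfg$founderHaplotypes, max(seg), replace = TRUE)[seg]
    out[i, ] <- skel$founders[cbind(tmpl, seq_len(m))]
  }
  out
}

skelToHaplotypeSet <- function(alleles, skel, cfg) {
  pops <- sprintf("pop%d", seq_len(cfg$nPopulations))
  nSamp <- cfg$nPopulations * cfg$haplotypesPerPopulation / 2L
  sampleIds <- sprintf("s%03d", seq_len(nSamp))
  popOfSample <- rep(pops, each = cfg$haplotypesPerPopulation / 2L)
  gr <- GRanges(skel$chrom, IRanges(skel$pos, width = 1L),
                ref = skel$ref, alt = skel$alt)
  HaplotypeSet(alleles, sampleIds, popOfSample, gr)
}

skelAncestralTable <- function(skel) {
  data.frame(chrom = skel$chrom, pos = skel$pos,
             ancestral = ifelse(skel$ancAllele == 1L, skel$alt, skel$ref),
             stringsAsFactors = FALSE)
}

#' Simulate a neutral multi-population haplotype panel
#'
#' Founder haplotypes are drawn per locus at frequencies uniform on
#' (0.05, 0.95); every present-day haplotype is a recombination mosaic of
#' the founders with geometric segment lengths (per-bp switch rate from the
#' configuration). All populations share the founder pool, so the panel is
#' exchangeable across populations (a null for both scans). The recorded
#' ancestral allele is the founder-majority allele (optionally
#' mis-assigned at a configured rate). Deterministic under the seed.
#'
#' @param cfg a [simConfig()] without a sweep.
#' @return list with `haplotypes` (a [HaplotypeSet-class]), `ancestral`
#'   (data.frame `chrom`, `pos`, `ancestral`), and `truth` (list: per-locus
#'   founder frequency `founderFreq`, `ancestralAllele` 0/1 coding, and
#'   per-haplotype `population`).
#' @export
simulateNeutral <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  set.seed(cfg$seed)
  skel <- simPanelSkeleton(cfg)
  nHap <- cfg$nPopulations * cfg$haplotypesPerPopulation
  alleles <- mosaicRows(nHap, skel, cfg)
  hs <- skelToHaplotypeSet(alleles, skel, cfg)
  list(haplotypes = hs,
       ancestral = skelAncestralTable(skel),
       truth = list(founderFreq = skel$u, ancestralAllele = skel$ancAllele,
                    population = haplotypePopulations(hs)))
}

#' Inject a hard selective sweep into a panel
#'
#' Emulates a completed-to-intermediate-frequency hard sweep structurally:
#' a fraction `frequency` of haplotypes (the carriers) receive the derived
#' allele at the core SNP nearest the requested position, and their entire
#' flanking region within `width/2` on each side is replaced by one shared
#' donor haplotype — the long identical haplotype that recent positive
#' selection leaves and that the iHS statistic targets. Non-carriers get
#' the ancestral core allele. Truth records the carriers and the core.
#'
#' @param panel result of [simulateNeutral()].
#' @param cfg the same [simConfig()], with `sweep` set.
#' @return the panel list with modified `haplotypes` and a `truth$sweep`
#'   entry (`chrom`, `position` of the chosen core SNP, `coreIndex`,
#'   `carriers`).
#' @export
injectSweep <- function(panel, cfg) {
  stopifnot(inherits(cfg, "simConfig"), !is.null(cfg$sweep))
  sw <- cfg$sweep
  hs <- panel$haplotypes
  gr <- variants(hs)
  if (sw$position < 1 || sw$position > cfg$chromLength)
    stop("sweep position outside the chromosome")
  onChrom <- which(as.character(seqnames(gr)) == as.character(sw$chrom))
  if (!length(onChrom)) stop("sweep chromosome has no variants")
  core <- onChrom[which.min(abs(start(gr)[onChrom] - sw$position))]
  corePos <- start(gr)[core]

  a <- alleleMatrix(hs)
  nHap <- nrow(a)
  nCar <- round(sw$frequency * nHap)
  carriers <- sample.int(nHap, nCar)
  region <- onChrom[abs(start(gr)[onChrom] - corePos) <= sw$width / 2]
  donor <- a[carriers[1], region]
  a[carriers, region] <- matrix(donor, nCar, length(region), byrow = TRUE)

  ancCore <- panel$truth$ancestralAllele[core]
  a[, core] <- ancCore                 # everyone ancestral ...
  a[carriers, core] <- 1L - ancCore    # ... except carriers: derived

  hs@alleles <- a
  panel$haplotypes <- hs
  panel$truth$sweep <- list(chrom = as.character(sw$chrom), position = corePos,
                            coreIndex = core, carriers = sort(carriers))
  panel
}

#' Differentiate populations under the F-model
#'
#' Starting from the neutral skeleton's per-locus ancestral frequency `p`,
#' each population draws its own frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` and its haplotype alleles are
#' resampled independently at that frequency. The Beta draw has mean `p`
#' and variance `F p (1 - p)`, so the expected Weir-Cockerham FST across
#' populations is approximately `F` (parameter-recovery validation for the
#' FST stage). Linkage structure is deliberately not preserved — this
#' generator validates the frequency-based scan, not the haplotype scan.
#'
#' @param cfg a [simConfig()] with `nPopulations >= 2`.
#' @return list as for [simulateNeutral()], with `truth$popFreq` the
#'   populations x loci matrix of realized frequencies.
#' @export
divergePopulations <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"), cfg$nPopulations >= 2)
  set.seed(cfg$seed + 1L)
  skel <- simPanelSkeleton(cfg)
  m <- length(skel$pos)
  Fd <- cfg$divergenceF
  shape <- (1 - Fd) / Fd
  popFreq <- matrix(stats::rbeta(cfg$nPopulations * m,
                                 rep(skel$u * shape, each = cfg$nPopulations),
                                 rep((1 - skel$u) * shape, each = cfg$nPopulations)),
                    nrow = cfg$nPopulations)
  nPer <- cfg$haplotypesPerPopulation
  alleles <- do.call(rbind, lapply(seq_len(cfg$nPopulations), function(k)
    matrix(stats::rbinom(nPer * m, 1L, rep(popFreq[k, ], each = nPer)),
           nrow = nPer)))
  hs <- skelToHaplotypeSet(alleles, skel, cfg)
  list(haplotypes = hs,
       ancestral = skelAncestralTable(skel),
       truth = list(founderFreq = skel$u, ancestralAllele = skel$ancAllele,
                    population = haplotypePopulations(hs), popFreq = popFreq))
}

#' Random gene catalogue
#'
#' Non-pathological random gene intervals (uniform starts, lengths uniform
#' in `lengthRange`, clipped to the chromosome), unique ids `gene0001` ...;
#' intervals may overlap analysis windows and each other arbitrarily.
#'
#' @param cfg a [simConfig()] (for seed and chromosome geometry).
#' @param nGenes number of genes (default 100).
#' @param lengthRange min/max gene length in bp (default 5-50 kb).
#' @return `GRanges` with `gene_id` and `symbol` columns.
#' @export
makeGeneCatalogue <- function(cfg, nGenes = 100L, lengthRange = c(5e3, 5e4)) {
  stopifnot(inherits(cfg, "simConfig"), all(lengthRange > 0))
  set.seed(cfg$seed + 2L)
  if (nGenes == 0L)
    return(GRanges(character(0), IRanges(integer(0), integer(0)),
                   gene_id = character(0), symbol = character(0)))
  ch <- sample(as.character(seq_len(cfg$nChromosomes)), nGenes, replace = TRUE)
  len <- round(stats::runif(nGenes, lengthRange[1], lengthRange[2]))
  st <- pmax(1, round(stats::runif(nGenes, 1, cfg$chromLength - len)))
  id <- sprintf("gene%04d", seq_len(nGenes))
  gr <- GRanges(ch, IRanges(st, st + len - 1), gene_id = id, symbol = id)
  sort(gr)
}

#' Synthetic pedigree with matings of known inbreeding
#'
#' Builds a pedigree of unrelated founders plus, per request, offspring of
#' one full-sib mating and one parent-offspring mating (both F = 0.25) and
#' a set of outbred offspring (F = 0), so downstream inbreeding
#' computations can be checked against exact values.
#'
#' @param cfg a [simConfig()] (seed only).
#' @param nFounders number of unrelated founders (default 8, minimum 4).
#' @param nOutbred number of outbred founder-pair offspring (default 4).
#' @param fullSib include a full-sib mating branch? (default `TRUE`)
#' @param parentOffspring include a parent-offspring mating branch?
#'   (default `TRUE`)
#' @return list with `pedigree` (data.frame `animal`, `sire`, `dam`) and
#'   `truth` (named expected F for the constructed inbred/outbred animals).
#' @export
makePedigree <- function(cfg, nFounders = 8L, nOutbred = 4L,
                         fullSib = TRUE, parentOffspring = TRUE) {
  stopifnot(inherits(cfg, "simConfig"), nFounders >= 4L)
  founders <- sprintf("f%02d", seq_len(nFounders))
  ped <- data.frame(animal = founders, sire = NA_character_,
                    dam = NA_character_, stringsAsFactors = FALSE)
  truth <- stats::setNames(rep(0, nFounders), founders)
  addRow <- function(animal, sire, dam, F = NA_real_) {
    ped <<- rbind(ped, data.frame(animal = animal, sire = sire, dam = dam,
                                  stringsAsFactors = FALSE))
    if (!is.na(F)) truth[animal] <<- F
  }
  for (k in seq_len(nOutbred))
    addRow(sprintf("o%02d", k), founders[1], founders[2], F = 0)
  if (fullSib) {
    addRow("sib1", founders[3], founders[4], F = 0)
    addRow("sib2", founders[3], founders[4], F = 0)
    addRow("fsOff", "sib1", "sib2", F = 0.25)
  }
  if (parentOffspring) {
    addRow("poChild", founders[1], founders[3], F = 0)
    addRow("poOff", founders[1], "poChild", F = 0.25)
  }
  list(pedigree = ped, truth = truth)
}

#' Write a simulated panel bundle to disk
#'
#' Emits the standard plain-text artifact set: phased VCF, population map
#' TSV, ancestral-allele TSV, optional gene BED and pedigree TSV, and a
#' truth JSON. The VCF round-trips exactly through [readPhasedVcf()].
#'
#' @param panel a panel list from [simulateNeutral()] /
#'   [divergePopulations()] (optionally after [injectSweep()]).
#' @param dir output directory (created if needed).
#' @param genes optional `GRanges` from [makeGeneCatalogue()].
#' @param pedigree optional data.frame from [makePedigree()].
#' @return named character vector of the files written, invisibly.
#' @export
writePanel <- function(panel, dir, genes = NULL, pedigree = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hs <- panel$haplotypes
  files <- c(vcf = file.path(dir, "panel.vcf"),
             popmap = file.path(dir, "popmap.tsv"),
             ancestral = file.path(dir, "ancestral.tsv"),
             truth = file.path(dir, "truth.json"))
  writePhasedVcf(hs, files["vcf"])
  utils::write.table(data.frame(sample_id = sampleIds(hs),
                                population = populations(hs)),
                     files["popmap"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$ancestral, files["ancestral"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(panel$truth, files["truth"], auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(genes)) {
    files["genes"] <- file.path(dir, "genes.bed")
    g <- genes
    mcols(g) <- S4Vectors::DataFrame(name = mcols(genes)$gene_id)
    rtracklayer::export(g, files["genes"], format = "BED")
  }
  if (!is.null(pedigree)) {
    files["pedigree"] <- file.path(dir, "pedigree.tsv")
    ped <- pedigree
    ped$sire[is.na(ped$sire)] <- "."
    ped$dam[is.na(ped$dam)] <- "."
    utils::write.table(ped, files["pedigree"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(files)
}
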