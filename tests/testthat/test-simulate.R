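test_that("generators are pure functions of the configuration (seeded)", {
  cfg <- simConfig(seed = 101, nPopulations = 2, haplotypesPerPopulation = 10,
                   chromLength = 3e5)
  a <- simulateNeutral(cfg); b <- simulateNeutral(cfg)
  expect_identical(alleleMatrix(a$haplotypes), alleleMatrix(b$haplotypes))
  expect_identical(a$ancestral, b$ancestral)
  g1 <- makeGeneCatalogue(cfg, 20); g2 <- makeGeneCatalogue(cfg, 20)
  expect_identical(GenomicRanges::start(g1), GenomicRanges::start(g2))
  d1 <- divergePopulations(cfg); d2 <- divergePopulations(cfg)
  expect_identical(alleleMatrix(d1$haplotypes), alleleMatrix(d2$haplotypes))
})

test_that("zero switch rate copies founders verbatim", {
  cfg <- simConfig(seed = 7, nPopulations = 1, haplotypesPerPopulation = 10,
                   chromLength = 2e5, founderHaplotypes = 6,
                   mosaicSwitchRate = 0)
  sim <- simulateNeutral(cfg)
  a <- alleleMatrix(sim$haplotypes)
  set.seed(cfg$seed)
  skel <- haploSweep:::simPanelSkeleton(cfg)
  founderRows <- apply(skel$founders, 1, paste, collapse = "")
  expect_true(all(apply(a, 1, paste, collapse = "") %in% founderRows))
})

test_that("sweep carriers share one haplotype across the configured width", {
  cfg <- simConfig(seed = 8, nPopulations = 1, haplotypesPerPopulation = 40,
                   chromLength = 4e6,
                   sweep = list(chrom = "1", position = 2e6, frequency = 0.6,
                                width = 1e6))
  pan <- injectSweep(simulateNeutral(cfg), cfg)
  a <- alleleMatrix(pan$haplotypes)
  tr <- pan$truth$sweep
  expect_equal(length(tr$carriers), round(0.6 * 40))
  pos <- GenomicRanges::start(variants(pan$haplotypes))
  region <- which(abs(pos - tr$position) <= 5e5)
  carrierRows <- a[tr$carriers, region, drop = FALSE]
  expect_true(all(apply(carrierRows, 2, function(col) length(unique(col)) == 1)))
  # carriers carry the derived (non-ancestral) core allele, others ancestral
  anc <- pan$truth$ancestralAllele[tr$coreIndex]
  expect_true(all(a[tr$carriers, tr$coreIndex] == 1 - anc))
  expect_true(all(a[-tr$carriers, tr$coreIndex] == anc))
})

test_that("sweep position outside the chromosome is an error", {
  cfg <- simConfig(seed = 8, nPopulations = 1, haplotypesPerPopulation = 10,
                   chromLength = 1e5,
                   sweep = list(chrom = "1", position = 9e9, frequency = 0.5))
  expect_error(injectSweep(simulateNeutral(cfg), cfg), "outside")
})

test_that("a rare sweep core is excluded by the default MAF filter downstream", {
  cfg <- simConfig(seed = 9, nPopulations = 1, haplotypesPerPopulation = 100,
                   chromLength = 1e6,
                   sweep = list(chrom = "1", position = 5e5, frequency = 0.02,
                                width = 2e5))
  pan <- injectSweep(simulateNeutral(cfg), cfg)
  pol <- polarize(pan$haplotypes, pan$ancestral)$haplotypes
  rec <- ihsScan(pol)
  crow <- which(rec$pos == pan$truth$sweep$position)
  expect_equal(rec$reason[crow], "maf")
})

test_that("F-model divergence vanishes in the F -> 0 limit", {
  dv <- divergePopulations(simConfig(seed = 14, nPopulations = 3,
                                     haplotypesPerPopulation = 40,
                                     chromLength = 1e6, divergenceF = 1e-4))
  rec <- wcFst(dv$haplotypes)
  expect_lt(abs(mean(rec$theta[rec$valid])), 0.01)
})

test_that("a locus fixed opposite between populations ranks first in emp_p", {
  dv <- divergePopulations(simConfig(seed = 15, nPopulations = 2,
                                     haplotypesPerPopulation = 20,
                                     chromLength = 5e5, divergenceF = 0.05))
  hs <- dv$haplotypes
  a <- alleleMatrix(hs)
  ph <- haplotypePopulations(hs)
  a[, 5] <- ifelse(ph == "pop1", 1L, 0L)
  hs@alleles <- a
  rec <- empiricalPvalues(wcFst(hs))
  expect_equal(which.min(rec$emp_p), 5L)
  expect_equal(rec$fst[5], 1)
})

test_that("empty gene catalogue flows through annotation as empty sets", {
  cfg <- simConfig(seed = 16, nPopulations = 1, haplotypesPerPopulation = 10,
                   chromLength = 1e5)
  genes <- makeGeneCatalogue(cfg, nGenes = 0)
  expect_equal(length(genes), 0L)
  win <- data.frame(chrom = "1", start = 0, end = 5e5, significant = TRUE)
  expect_equal(genesInWindows(win, genes), character(0))
})

test_that("synthetic pedigree truth is recovered by the inbreeding computation", {
  cfg <- simConfig(seed = 17, nPopulations = 1, haplotypesPerPopulation = 10,
                   chromLength = 1e5)
  mp <- makePedigree(cfg)
  F <- inbreedingCoefficients(mp$pedigree)
  expect_equal(unname(F[names(mp$truth)]), unname(mp$truth))
})

test_that("the written bundle reproduces the in-memory panel exactly", {
  cfg <- simConfig(seed = 18, nPopulations = 2, haplotypesPerPopulation = 10,
                   chromLength = 2e5)
  sim <- simulateNeutral(cfg)
  dir <- withr::local_tempdir()
  files <- writePanel(sim, dir, genes = makeGeneCatalogue(cfg, 10),
                      pedigree = makePedigree(cfg)$pedigree)
  expect_true(all(file.exists(files)))
  back <- readPhasedVcf(files[["vcf"]], files[["popmap"]])
  expect_identical(alleleMatrix(back), alleleMatrix(sim$haplotypes))
  anc <- readAncestralTable(files[["ancestral"]])
  expect_equal(anc$pos, sim$ancestral$pos)
  ped <- readPedigree(files[["pedigree"]])
  expect_equal(ped$animal, makePedigree(cfg)$pedigree$animal)
  expect_true(is.na(ped$sire[1]))
})
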