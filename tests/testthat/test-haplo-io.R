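writeToyVcf <- function(lines, samples = c("s1", "s2")) {
  path <- withr::local_tempfile(fileext = ".vcf",
                                .local_envir = parent.frame())
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, lines), path)
  path
}

toyPopMap <- data.frame(sample_id = c("s1", "s2"),
                        population = c("A", "B"))

test_that("phased VCF ingestion builds an aligned matrix and variant table", {
  path <- writeToyVcf(c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1",
    "1\t300\t.\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|0"))
  hs <- readPhasedVcf(path, toyPopMap)
  expect_s4_class(hs, "HaplotypeSet")
  expect_equal(dim(alleleMatrix(hs)), c(4L, 3L))
  expect_equal(nVariants(hs), 3L)
  expect_equal(start(variants(hs)), c(100L, 200L, 300L))
  # haplotype rows: s1 phase0, s1 phase1, s2 phase0, s2 phase1
  expect_equal(alleleMatrix(hs)[, 1], c(0L, 1L, 1L, 1L))
  expect_equal(populations(hs), c("A", "B"))
  expect_equal(haplotypePopulations(hs), c("A", "A", "B", "B"))
})

test_that("missing or unphased genotypes are ingestion errors naming the record", {
  miss <- writeToyVcf(c(
    "1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t./.\t0|1"))
  expect_error(readPhasedVcf(miss, toyPopMap), "1:200.*s1")
  unph <- writeToyVcf("1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1")
  expect_error(readPhasedVcf(unph, toyPopMap), "unphased|missing")
})

test_that("non-biallelic-SNP records are skipped with a warning", {
  path <- writeToyVcf(c(
    "1\t100\t.\tA\tG,T\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t150\t.\tAT\tA\t.\tPASS\t.\tGT\t0|1\t1|1",
    "1\t200\t.\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1"))
  expect_warning(hs <- readPhasedVcf(path, toyPopMap), "skipped 2")
  expect_equal(nVariants(hs), 1L)
  expect_equal(attr(hs, "nSkipped"), 2L)
})

test_that("a synthetic panel round-trips through VCF exactly", {
  cfg <- simConfig(seed = 77, nPopulations = 2, haplotypesPerPopulation = 10,
                   chromLength = 2e5)
  sim <- simulateNeutral(cfg)
  dir <- withr::local_tempdir()
  files <- writePanel(sim, dir)
  hs2 <- readPhasedVcf(files[["vcf"]], files[["popmap"]])
  expect_identical(alleleMatrix(hs2), alleleMatrix(sim$haplotypes))
  expect_identical(start(variants(hs2)), start(variants(sim$haplotypes)))
  expect_identical(populations(hs2), populations(sim$haplotypes))
})

test_that("call-rate filtering removes variants below the threshold", {
  hs <- toyPanel(matrix(c(0, 1, 1, 0, 0, 1, 1, 1), nrow = 4), polarized = FALSE)
  GenomicRanges::mcols(hs@variants)$callRate <- c(0.85, 0.95)
  res <- applyQc(hs, minCallRate = 0.90)
  expect_equal(res$report$n_removed_callrate, 1L)
  expect_equal(nVariants(res$haplotypes), 1L)
  expect_equal(start(variants(res$haplotypes)), 2000L)
  # threshold is strict "below": 0.90 itself is retained
  GenomicRanges::mcols(hs@variants)$callRate <- c(0.90, 0.95)
  expect_equal(applyQc(hs, minCallRate = 0.90)$report$n_removed_callrate, 0L)
})

test_that("monomorphic variants are removed and counts reconcile", {
  a <- cbind(c(0, 0, 0, 0), c(1, 1, 1, 1), c(0, 1, 0, 1))
  hs <- toyPanel(a, polarized = FALSE)
  res <- applyQc(hs)
  expect_equal(res$report$n_removed_monomorphic, 2L)
  expect_equal(res$report$n_retained, 1L)
  expect_equal(res$report$n_input,
               with(res$report, n_retained + n_removed_callrate +
                      n_removed_monomorphic + n_removed_mendelian +
                      n_removed_unpolarized))
  expect_error(applyQc(toyPanel(matrix(0, 4, 2), polarized = FALSE)),
               "empty panel")
})

test_that("Mendelian-impossible trios remove the variant", {
  # s1 = child 1|1, s2 = sire 0|0, s3 = dam 0|0 at variant 1 (impossible);
  # variant 2 is consistent (child het, sire hom-alt).
  a <- rbind(c(1, 1), c(1, 0),   # child
             c(0, 1), c(0, 1),   # sire
             c(0, 0), c(0, 0))   # dam
  hs <- toyPanel(a, pops = rep("A", 3), polarized = FALSE)
  trios <- data.frame(child = "s1", sire = "s2", dam = "s3")
  res <- applyQc(hs, dropMonomorphic = FALSE, trios = trios)
  expect_equal(res$report$n_removed_mendelian, 1L)
  expect_equal(start(variants(res$haplotypes)), 2000L)
})

test_that("polarization flips coding so 1 = derived and drops unmatched", {
  a <- cbind(c(0, 1, 1, 0), c(0, 1, 1, 1), c(0, 0, 1, 1))
  hs <- toyPanel(a, polarized = FALSE)
  GenomicRanges::mcols(hs@variants)$ref <- c("A", "A", "A")
  GenomicRanges::mcols(hs@variants)$alt <- c("G", "G", "G")
  anc <- data.frame(chrom = "1", pos = c(1000L, 2000L, 3000L),
                    ancestral = c("A", "G", "C"))
  res <- polarize(hs, anc)
  expect_equal(res$report$n_removed_unpolarized, 1L)  # ancestral C matches neither
  expect_equal(nVariants(res$haplotypes), 2L)
  m <- alleleMatrix(res$haplotypes)
  expect_equal(m[, 1], a[, 1])               # ancestral = ref: unchanged
  expect_equal(m[, 2], 1L - a[, 2])          # ancestral = alt: bit-flipped
  df <- GenomicRanges::mcols(variants(res$haplotypes))$derivedFreq
  expect_equal(df, c(mean(a[, 1]), 1 - mean(a[, 2])))
  expect_true(isPolarized(res$haplotypes))
})

test_that("polarizing twice with swapped ancestral assignment restores coding", {
  a <- cbind(c(0, 1, 1, 0), c(0, 1, 1, 1))
  hs <- toyPanel(a, polarized = FALSE)
  GenomicRanges::mcols(hs@variants)$ref <- c("A", "A")
  GenomicRanges::mcols(hs@variants)$alt <- c("G", "G")
  ancAlt <- data.frame(chrom = "1", pos = c(1000L, 2000L),
                       ancestral = c("G", "G"))
  ancRef <- data.frame(chrom = "1", pos = c(1000L, 2000L),
                       ancestral = c("A", "A"))
  once <- polarize(hs, ancAlt)$haplotypes      # G ancestral: flips coding
  expect_equal(alleleMatrix(once), 1L - a)
  twice <- polarize(once, ancRef)$haplotypes   # swapped assignment: flips back
  expect_equal(alleleMatrix(twice), a)
})

test_that("every variant retained after QC is truly polymorphic", {
  sim <- simulateNeutral(simConfig(seed = 5, nPopulations = 2,
                                   haplotypesPerPopulation = 10,
                                   chromLength = 1e5))
  res <- applyQc(sim$haplotypes)
  pol <- polarize(res$haplotypes, sim$ancestral)$haplotypes
  df <- GenomicRanges::mcols(variants(pol))$derivedFreq
  expect_true(all(df > 0 & df < 1))
})
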