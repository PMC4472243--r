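test_that("EHH is 1 everywhere when all carriers are identical", {
  a <- matrix(rep(c(1, 1, 0, 0), 5), nrow = 4)  # two derived carriers, identical
  hs <- toyPanel(a)
  pr <- computeEhh(hs, core = 3, allele = "derived", decayFloor = 0.05)
  expect_true(all(pr@ehh == 1))
  expect_equal(pr@stopReason, c("edge", "edge"))
})

test_that("a {2,1,1} split yields EHH = C(2,2)/C(4,2) = 1/6", {
  # carriers split over two flanking markers: after marker 3 alone the
  # groups are {1,2} vs {3,4}; marker 4 separates 3 from 4. EHH at marker 4
  # = 1/6 (only the pair 1-2 remains identical through both markers).
  a <- rbind(c(1, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1),
             c(0, 0, 0), c(0, 0, 0))
  hs <- toyPanel(a)
  pr <- computeEhh(hs, core = 1, allele = "derived", decayFloor = 0)
  expect_equal(pr@ehh[match(2000L, pr@positions)], 2 / 6)  # groups {2,2}
  expect_equal(pr@ehh[match(3000L, pr@positions)], 1 / 6)  # groups {2,1,1}
})

test_that("two carriers differing at the adjacent marker stop at EHH 0", {
  a <- rbind(c(1, 0), c(1, 1), c(0, 0), c(0, 0))
  hs <- toyPanel(a)
  pr <- computeEhh(hs, core = 1, allele = "derived")
  expect_equal(pr@ehh, c(1, 0))
  expect_equal(pr@stopReason, c("edge", "floor"))  # left flank: chromosome start
})

test_that("fewer than two carriers is not scorable", {
  a <- rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0))
  expect_error(computeEhh(toyPanel(a), core = 1, allele = "derived"),
               "not scorable")
})

test_that("EHH matches exhaustive pair enumeration on random panels and is monotone", {
  for (s in 1:25) {
    hs <- randomPanel(nHap = sample(4:10, 1) * 2 %/% 2, nVar = sample(6:20, 1),
                      seed = s)
    a <- alleleMatrix(hs)
    pos <- start(variants(hs))
    core <- sample(ncol(a), 1)
    for (al in c(0L, 1L)) {
      if (sum(a[, core] == al) < 2) next
      pr <- computeEhh(hs, core, if (al == 1L) "derived" else "ancestral",
                       decayFloor = 0.05)
      or <- ehhOracle(a, pos, core, al, decayFloor = 0.05)
      expect_equal(pr@ehh, c(rev(or$left$ehh), 1, or$right$ehh),
                   tolerance = 1e-12)
      expect_equal(pr@stopReason, c(or$left$reason, or$right$reason))
      # monotone non-increasing outward on each flank
      coreAt <- match(pr@corePosition, pr@positions)
      expect_true(all(diff(pr@ehh[coreAt:length(pr@ehh)]) <= 1e-12))
      expect_true(all(diff(rev(pr@ehh[1:coreAt])) <= 1e-12))
      expect_true(all(pr@ehh >= 0 & pr@ehh <= 1))
    }
  }
})

test_that("trapezoid integration matches hand-computed areas", {
  # piecewise-linear toy: EHH 1 at core, 0.5 at +/-10 kb, 0.04 at +/-20 kb,
  # floor 0.05: per flank 7500 + (0.5+0.05)/2 * 10000*(0.45/0.46)
  mk <- function() new("EhhProfile", coreIndex = 2L, corePosition = 20000L,
                       allele = "derived",
                       positions = c(0L, 10000L, 20000L, 30000L, 40000L),
                       ehh = c(0.04, 0.5, 1, 0.5, 0.04),
                       stopReason = c("floor", "floor"), nCarriers = 4L)
  flank <- 7500 + (0.5 + 0.05) / 2 * 10000 * (0.5 - 0.05) / (0.5 - 0.04)
  res <- integrateIhh(mk(), decayFloor = 0.05)
  expect_true(res$valid)
  expect_equal(res$ihh, 2 * flank, tolerance = 1e-12)
})

test_that("edge- and gap-truncated profiles are invalid (edge overridable)", {
  edge <- new("EhhProfile", coreIndex = 1L, corePosition = 1000L,
              allele = "derived", positions = c(1000L, 2000L),
              ehh = c(1, 0.8), stopReason = c("edge", "floor"),
              nCarriers = 4L)
  res <- integrateIhh(edge)
  expect_false(res$valid)
  expect_equal(res$reason, "edge")
  expect_true(integrateIhh(edge, edgeRule = "integrate")$valid)
  gap <- new("EhhProfile", coreIndex = 1L, corePosition = 1000L,
             allele = "derived", positions = c(1000L, 2000L),
             ehh = c(1, 0.8), stopReason = c("gap", "floor"), nCarriers = 4L)
  expect_equal(integrateIhh(gap)$reason, "gap")
  expect_false(integrateIhh(gap, edgeRule = "integrate")$valid)
})

test_that("integration to the floor matches the pair-enumeration oracle end to end", {
  for (s in 1:10) {
    hs <- randomPanel(nHap = 10, nVar = 20, seed = 100 + s)
    a <- alleleMatrix(hs); pos <- start(variants(hs))
    core <- 10L
    for (al in c(0L, 1L)) {
      if (sum(a[, core] == al) < 2) next
      pr <- computeEhh(hs, core, if (al == 1L) "derived" else "ancestral")
      res <- integrateIhh(pr)
      or <- ehhOracle(a, pos, core, al)
      if (or$left$reason == "floor" && or$right$reason == "floor") {
        expect_true(res$valid)
        expected <- ihhOracleFlank(pos[core], or$left) +
          ihhOracleFlank(pos[core], or$right)
        expect_equal(res$ihh, expected, tolerance = 1e-12)
      } else {
        expect_false(res$valid)
      }
    }
  }
})

test_that("the compiled scan agrees with the reference path", {
  hs <- randomPanel(nHap = 20, nVar = 40, seed = 42)
  rec <- ihsScan(hs, mafMin = 0)
  a <- alleleMatrix(hs); pos <- start(variants(hs))
  for (core in seq_len(nVariants(hs))) {
    for (al in c(0L, 1L)) {
      col <- if (al == 0L) "ihh_a" else "ihh_d"
      if (sum(a[, core] == al) < 2) {
        expect_true(is.na(rec[[col]][core]))
        next
      }
      pr <- computeEhh(hs, core, if (al == 1L) "derived" else "ancestral")
      res <- integrateIhh(pr)
      if (res$valid) expect_equal(rec[[col]][core], res$ihh, tolerance = 1e-12)
      else expect_true(is.na(rec[[col]][core]))
    }
  }
})

test_that("raw iHS identities and sign semantics hold", {
  expect_equal(rawIhs(5e5, 5e5), 0)
  expect_equal(rawIhs(exp(1) * 3e5, 3e5), 1)
  expect_true(is.na(rawIhs(0, 1e5)))
  expect_true(is.na(rawIhs(NA, 1e5)))
  # swapping ancestral/derived labels negates the raw score exactly
  expect_equal(rawIhs(2e5, 7e5), -rawIhs(7e5, 2e5))
})

test_that("a hard sweep on the derived allele gives negative raw iHS at the core", {
  cfg <- simConfig(seed = 21, nPopulations = 1, haplotypesPerPopulation = 60,
                   chromLength = 4e6,
                   sweep = list(chrom = "1", position = 2e6, frequency = 0.6,
                                width = 8e5))
  pan <- injectSweep(simulateNeutral(cfg), cfg)
  pol <- polarize(pan$haplotypes, pan$ancestral)$haplotypes
  rec <- ihsScan(pol)
  core <- pan$truth$sweep$coreIndex
  # core index refers to the pre-polarization table; map by position
  crow <- which(rec$pos == pan$truth$sweep$position)
  expect_true(rec$valid[crow])
  expect_lt(rec$raw[crow], 0)
})

test_that("standardization gives mean 0, sd 1 within each bin", {
  hs <- randomPanel(nHap = 40, nVar = 200, seed = 9)
  rec <- ihsScan(hs, mafMin = 0)
  std <- standardizeIhs(rec, nBins = 4, minPerBin = 5)
  ok <- std$records$valid & !is.na(std$records$ihs)
  # left-closed merged bins, as the implementation assigns them
  bin <- findInterval(std$records$derived_freq[ok], std$bins$lower)
  mus <- tapply(std$records$ihs[ok], bin, mean)
  sds <- tapply(std$records$ihs[ok], bin, sd)
  expect_equal(as.integer(table(bin)), std$bins$n)
  expect_true(all(abs(mus) < 1e-9))
  expect_true(all(abs(sds[!is.na(sds)] - 1) < 1e-9))
  # each record's score is its raw score centred/scaled by its bin
  one <- std$records[ok, ][1, ]
  b <- findInterval(one$derived_freq, std$bins$lower)
  expect_equal((one$raw - std$bins$mean[b]) / std$bins$sd[b], one$ihs)
})

test_that("underfilled frequency bins are merged with a neighbour", {
  set.seed(31)
  rec <- data.frame(raw = rnorm(100), derived_freq = c(runif(98, 0.4, 0.6), 0.95, 0.96),
                    valid = TRUE)
  std <- standardizeIhs(rec, nBins = 10, minPerBin = 10)
  expect_true(all(std$bins$n >= 10 | nrow(std$bins) == 1))
  expect_true(all(!is.na(std$records$ihs)))
})

test_that("Gaussian transform: ihs 0 gives p 1; p falls as |ihs| grows; sign-symmetric", {
  r <- ihsPvalues(c(0, 1.5, -1.5, 3, 7))
  expect_equal(r$p_two_sided[1], 1)
  expect_equal(r$p_ihs[1], 0)
  expect_equal(r$p_two_sided[2], r$p_two_sided[3])
  expect_true(all(diff(r$p_two_sided[c(1, 2, 4, 5)]) < 0))
  expect_equal(r$p_ihs, -log10(r$p_two_sided))
})

test_that("the p transform reproduces printed per-window P values", {
  p <- ihsPvalues(c(7.000, 6.142))$p_two_sided
  expect_equal(signif(p[1], 3), 2.56e-12)
  expect_equal(signif(p[2], 3), 8.15e-10)
})
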