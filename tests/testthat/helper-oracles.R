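# Independent brute-force oracles and tiny panel builders. These are kept
# deliberately naive (explicit loops, pair enumeration) so they share no
# code path with the package implementations they check.

# Build a HaplotypeSet from a raw matrix. One chromosome unless chrom given.
toyPanel <- function(alleles, pos = NULL, pops = NULL, chrom = NULL,
                     polarized = TRUE) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  m <- ncol(alleles)
  nSamp <- nrow(alleles) / 2
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pops)) pops <- rep("A", nSamp)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
                               ref = rep("A", m), alt = rep("G", m))
  if (polarized)
    GenomicRanges::mcols(gr)$derivedFreq <- colMeans(alleles)
  HaplotypeSet(alleles, sampleIds = sprintf("s%d", seq_len(nSamp)),
               populations = pops, variants = gr, polarized = polarized)
}

# EHH by exhaustive pair enumeration: at marker m, the fraction of carrier
# pairs identical at every marker between core and m (inclusive). Returns
# per-flank positions/values with the same stopping rules as the package.
ehhOracle <- function(alleles, pos, core, alleleValue, decayFloor = 0.05,
                      maxGap = 2e5) {
  carriers <- which(alleles[, core] == alleleValue)
  nc <- length(carriers)
  stopifnot(nc >= 2)
  pairs <- utils::combn(carriers, 2)
  scan <- function(dir) {
    lim <- if (dir < 0) 1L else ncol(alleles)
    out <- list(pos = integer(0), ehh = numeric(0), reason = "edge")
    prevPos <- pos[core]
    m <- core + dir
    while (if (dir < 0) m >= lim else m <= lim) {
      if (abs(pos[m] - prevPos) > maxGap) { out$reason <- "gap"; return(out) }
      span <- if (dir < 0) m:core else core:m
      same <- 0
      for (k in seq_len(ncol(pairs))) {
        if (all(alleles[pairs[1, k], span] == alleles[pairs[2, k], span]))
          same <- same + 1
      }
      e <- same / ncol(pairs)
      out$pos <- c(out$pos, pos[m]); out$ehh <- c(out$ehh, e)
      if (e < decayFloor) { out$reason <- "floor"; return(out) }
      prevPos <- pos[m]
      m <- m + dir
    }
    out
  }
  list(left = scan(-1L), right = scan(+1L))
}

# Trapezoid integration of an oracle flank (values outward from the core),
# with interpolation to the decay-floor crossing; independent arithmetic.
ihhOracleFlank <- function(corePos, flank, decayFloor = 0.05) {
  p <- c(corePos, flank$pos); e <- c(1, flank$ehh)
  area <- 0
  for (k in seq_along(p)[-1]) {
    gap <- abs(p[k] - p[k - 1])
    if (e[k] >= decayFloor) {
      area <- area + (e[k - 1] + e[k]) / 2 * gap
    } else {
      dx <- gap * (e[k - 1] - decayFloor) / (e[k - 1] - e[k])
      area <- area + (e[k - 1] + decayFloor) / 2 * dx
      break
    }
  }
  area
}

# Weir-Cockerham 1984 haploid theta by explicit ANOVA sums of squares.
wcOracle <- function(alleles, popOfHap) {
  pops <- unique(popOfHap)
  r <- length(pops)
  m <- ncol(alleles)
  theta <- numeric(m)
  for (j in seq_len(m)) {
    x <- alleles[, j]
    ni <- numeric(r); pi <- numeric(r)
    for (k in seq_len(r)) {
      rows <- popOfHap == pops[k]
      ni[k] <- sum(rows)
      pi[k] <- mean(x[rows])
    }
    N <- sum(ni)
    pbar <- sum(ni * pi) / N
    SSP <- 0; SSG <- 0
    for (k in seq_len(r)) {
      SSP <- SSP + ni[k] * (pi[k] - pbar)^2
      rows <- which(popOfHap == pops[k])
      for (i in rows) SSG <- SSG + (x[i] - pi[k])^2
    }
    MSP <- SSP / (r - 1)
    MSG <- SSG / (N - r)
    nc <- (N - sum(ni^2) / N) / (r - 1)
    denom <- MSP + (nc - 1) * MSG
    theta[j] <- if (denom == 0) NA_real_ else (MSP - MSG) / denom
  }
  theta
}

# Random small polarized panel for property tests.
randomPanel <- function(nHap = 8, nVar = 12, nPops = 1, seed = 1) {
  set.seed(seed)
  nHap <- 2 * ceiling(nHap / 2)
  a <- matrix(rbinom(nHap * nVar, 1L, runif(nVar, 0.2, 0.8)[rep(seq_len(nVar),
              each = nHap)]), nrow = nHap)
  pos <- sort(sample.int(nVar * 5000L, nVar))
  pops <- rep(sprintf("p%d", seq_len(nPops)), length.out = nHap / 2)
  toyPanel(a, pos = pos, pops = pops)
}
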