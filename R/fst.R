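#' Per-SNP global Weir-Cockerham FST
#'
#' The multi-population (global) Weir-Cockerham method-of-moments estimator
#' of the fixation index, computed per variant from the 1984 variance-
#' component formulas with sample-size weighting (unequal population sizes
#' handled through the n_c correction). The default haploid mode treats
#' each phased haplotype as an independent gamete, so the within-individual
#' component collapses: with mean squares among populations
#' `MSP = sum_i n_i (p_i - p_bar)^2 / (r - 1)` and within
#' `MSG = sum_i n_i p_i (1 - p_i) / (N - r)`, the components are
#' `a = (MSP - MSG) / n_c` (among-population), `b = 0`, `c = MSG`, and
#' `theta = a / (a + b + c)`. The diploid mode applies the full 1984
#' a/b/c decomposition using observed heterozygosity from each sample's
#' phased genotype pair.
#'
#' Negative theta estimates (no biological interpretation) are clipped to 0
#' in the `fst` column; the unclipped `theta` is kept. Variants monomorphic
#' across all populations have undefined theta and are flagged invalid
#' (excluded from ranking).
#'
#' @param x a [HaplotypeSet-class] with at least two populations.
#' @param mode `"haploid"` (default; haplotype-level) or `"diploid"`.
#' @return data.frame per variant: `chrom`, `pos`, `a`, `b`, `c`, `theta`,
#'   `fst` (= `max(theta, 0)`), `valid`.
#' @examples
#' sim <- divergePopulations(simConfig(seed = 9, nPopulations = 3,
#'   haplotypesPerPopulation = 30, chromLength = 2e5, divergenceF = 0.1))
#' summary(wcFst(sim$haplotypes)$fst)
#' @export
wcFst <- function(x, mode = c("haploid", "diploid")) {
  mode <- match.arg(mode)
  popHap <- haplotypePopulations(x)
  pops <- unique(popHap)
  r <- length(pops)
  if (r < 2) stop("global FST needs at least 2 populations")
  a <- alleleMatrix(x)
  gr <- variants(x)

  if (mode == "haploid") {
    ni <- as.numeric(table(popHap)[pops])        # haplotypes per population
    N <- sum(ni)
    pmat <- do.call(rbind, lapply(pops, function(pp)
      colMeans(a[popHap == pp, , drop = FALSE])))      # r x m
    pbar <- as.numeric(crossprod(ni, pmat)) / N
    MSP <- as.numeric(crossprod(ni, (pmat - matrix(pbar, r, ncol(a),
                                                   byrow = TRUE))^2)) / (r - 1)
    MSG <- as.numeric(crossprod(ni, pmat * (1 - pmat))) / (N - r)
    nc <- (N - sum(ni^2) / N) / (r - 1)
    comp_a <- (MSP - MSG) / nc
    comp_b <- rep(0, ncol(a))
    comp_c <- MSG
  } else {
    d <- dosageMatrix(x)                         # samples x m
    popS <- populations(x)
    ni <- as.numeric(table(popS)[pops])          # individuals per population
    N <- sum(ni)
    pmat <- do.call(rbind, lapply(pops, function(pp)
      colMeans(d[popS == pp, , drop = FALSE]) / 2))
    hmat <- do.call(rbind, lapply(pops, function(pp)
      colMeans(d[popS == pp, , drop = FALSE] == 1L)))  # observed het freq
    nbar <- N / r
    nc <- (N - sum(ni^2) / N) / (r - 1)
    pbar <- as.numeric(crossprod(ni, pmat)) / N
    s2 <- as.numeric(crossprod(ni, (pmat - matrix(pbar, r, ncol(d),
                                                  byrow = TRUE))^2)) /
      ((r - 1) * nbar)
    hbar <- as.numeric(crossprod(ni, hmat)) / N
    comp_a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    comp_b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    comp_c <- hbar / 2
  }

  denom <- comp_a + comp_b + comp_c
  mono <- colSums(a) == 0L | colSums(a) == nrow(a)
  theta <- ifelse(!mono & denom != 0, comp_a / denom, NA_real_)
  data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
             a = comp_a, b = comp_b, c = comp_c,
             theta = theta, fst = pmax(theta, 0),
             valid = !is.na(theta), stringsAsFactors = FALSE)
}

#' Rank-based empirical p-values for FST
#'
#' `emp_p = rank / N` over the valid records, with rank 1 for the largest
#' clipped `fst` and ties sharing the maximum rank of their block (the
#' conservative convention: a tie never gains a smaller p than its worst
#' member). Invalid (monomorphic) records keep `emp_p = NA` and do not
#' enter `N`.
#'
#' @param records data.frame from [wcFst()].
#' @return the records with an `emp_p` column added; order preserved.
#' @export
empiricalPvalues <- function(records) {
  records$emp_p <- NA_real_
  ok <- records$valid
  N <- sum(ok)
  if (N > 0)
    records$emp_p[ok] <- rank(-records$fst[ok], ties.method = "max") / N
  records
}

#' Flag the top fraction of FST values as selection signatures
#'
#' Records with `emp_p <= fraction` are flagged; every record tied at the
#' boundary `fst` value is included, so a tie block straddling the cutoff
#' is flagged whole. With `N` distinct values and fraction `f`, exactly
#' `floor(N * f)` records are flagged (none when `1/N > f`).
#'
#' @param records data.frame from [empiricalPvalues()].
#' @param fraction top fraction to call (default 0.001, i.e. the top 0.1%).
#' @return the records with a logical `top` column added.
#' @export
callTopFraction <- function(records, fraction = 0.001) {
  stopifnot(!is.null(records$emp_p))
  records$top <- FALSE
  ok <- records$valid & !is.na(records$emp_p)
  k <- floor(sum(ok) * fraction)   # the cutoff rank; emp_p of rank k is k/N <= fraction
  if (k >= 1) {
    boundary <- sort(records$fst[ok], decreasing = TRUE)[k]
    records$top <- ok & records$fst >= boundary
  }
  records
}

#' Summarize a genome FST scan
#'
#' Mean clipped FST over defined records, the Wright differentiation
#' category of that mean (little < 0.05; moderate 0.05-0.15; great
#' 0.15-0.25; very great > 0.25), and counts of SNPs in the high-FST
#' magnitude bins `[0.5,0.6), [0.6,0.7), [0.7,0.8), [0.8,0.9), [0.9,1]`.
#'
#' @param records data.frame from [wcFst()].
#' @return list with `mean_fst`, `classification`, and `bin_counts`
#'   (named integer vector over the five high-FST bins).
#' @export
summarizeFst <- function(records) {
  f <- records$fst[records$valid]
  if (!length(f)) stop("no defined FST records to summarize")
  m <- mean(f)
  classification <-
    if (m < 0.05) "little"
    else if (m <= 0.15) "moderate"
    else if (m <= 0.25) "great"
    else "very great"
  edges <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  counts <- vapply(seq_along(edges), function(k) {
    hi <- if (k < length(edges)) edges[k + 1] else 1.0000001
    sum(f >= edges[k] & f < hi)
  }, integer(1))
  names(counts) <- c("[0.5,0.6)", "[0.6,0.7)", "[0.7,0.8)", "[0.8,0.9)",
                     "[0.9,1]")
  list(mean_fst = m, classification = classification, bin_counts = counts)
}

#' Write top FST SNPs as BED
#'
#' @param records called records ([callTopFraction()]).
#' @param path output BED path (0-based half-open single-bp features).
#' @return `path`, invisibly.
#' @export
writeTopFstBed <- function(records, path) {
  top <- records[records$top, , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\tfst\t%g", top$chrom, top$pos - 1L,
                     top$pos, top$fst), path)
  invisible(path)
}
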