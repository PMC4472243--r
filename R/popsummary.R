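#' Pedigree inbreeding coefficients
#'
#' Wright's inbreeding coefficient for every animal in a pedigree, by the
#' recursive tabular (numerator-relationship) method: F of an animal equals
#' the kinship of its parents, with `a_xy = (a_{y,sire(x)} + a_{y,dam(x)})/2`
#' for `y` preceding `x` and `a_xx = 1 + a_{sire(x),dam(x)}/2`. Founders and
#' unknown parents are treated as unrelated non-inbred individuals (F = 0).
#' The pedigree must be acyclic; a cycle is an error naming its members.
#'
#' @param ped data.frame with columns `animal`, `sire`, `dam` (`NA` =
#'   unknown parent), in any row order.
#' @return named numeric vector of F per animal, in `[0, 1)`.
#' @examples
#' ped <- data.frame(animal = c("a", "b", "x", "y", "z"),
#'                   sire = c(NA, NA, "a", "a", "x"),
#'                   dam  = c(NA, NA, "b", "b", "y"))
#' inbreedingCoefficients(ped)["z"]  # full-sib mating offspring: 0.25
#' @export
inbreedingCoefficients <- function(ped) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(ped)))
  ids <- as.character(ped$animal)
  if (anyDuplicated(ids)) stop("duplicate animal ids in pedigree")
  parents <- cbind(as.character(ped$sire), as.character(ped$dam))
  parents[!(parents %in% ids)] <- NA  # parents without own records = founders

  # topological order (parents before offspring); detects cycles
  n <- length(ids)
  si <- match(parents[, 1], ids); di <- match(parents[, 2], ids)
  placed <- logical(n); ord <- integer(0)
  parentPlaced <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  repeat {
    ready <- !placed & parentPlaced(si) & parentPlaced(di)
    if (!any(ready)) break
    ord <- c(ord, which(ready)); placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree cycle involving: ", paste(ids[!placed], collapse = ", "))

  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (k in ord) {
    s <- si[k]; d <- di[k]
    for (jj in ord) {
      if (jj == k) break
      A[k, jj] <- A[jj, k] <-
        ((if (is.na(s)) 0 else A[jj, s]) + (if (is.na(d)) 0 else A[jj, d])) / 2
    }
    A[k, k] <- 1 + (if (is.na(s) || is.na(d)) 0 else A[s, d] / 2)
  }
  stats::setNames(diag(A) - 1, ids)
}

#' Pairwise Euclidean genotype distances
#'
#' Each sample is represented by its allele-dosage vector (0/1/2 per
#' variant); the matrix of pairwise Euclidean distances between these
#' vectors summarizes genomic relationships (e.g. population clustering).
#'
#' @param x a [HaplotypeSet-class].
#' @return symmetric numeric matrix (samples x samples) with zero diagonal.
#' @export
euclideanDistanceMatrix <- function(x) {
  as.matrix(stats::dist(dosageMatrix(x)))
}

#' Minor-allele-frequency summary
#'
#' Mean and standard deviation of the per-SNP minor allele frequency,
#' overall and (optionally) per population.
#'
#' @param x a [HaplotypeSet-class].
#' @param perPopulation also summarize within each population?
#' @return data.frame `population` (`"all"` plus labels), `n_snps`,
#'   `mean_maf`, `sd_maf`.
#' @export
mafSummary <- function(x, perPopulation = TRUE) {
  a <- alleleMatrix(x)
  mafOf <- function(rows) {
    f <- colMeans(a[rows, , drop = FALSE])
    pmin(f, 1 - f)
  }
  groups <- list(all = seq_len(nrow(a)))
  if (perPopulation) {
    ph <- haplotypePopulations(x)
    for (pp in unique(ph)) groups[[pp]] <- which(ph == pp)
  }
  do.call(rbind, lapply(names(groups), function(g) {
    maf <- mafOf(groups[[g]])
    data.frame(population = g, n_snps = length(maf),
               mean_maf = mean(maf), sd_maf = stats::sd(maf),
               stringsAsFactors = FALSE)
  }))
}

#' Mean adjacent-SNP spacing from panel totals
#'
#' The mean distance between adjacent SNPs given a total spanned length,
#' the SNP count and the number of chromosomes: each chromosome contributes
#' one fewer gap than it has SNPs, so
#' `spacing = span / (nSnps - nChromosomes)`.
#'
#' @param spanBp total spanned length in bp.
#' @param nSnps number of SNPs.
#' @param nChromosomes number of chromosomes the SNPs sit on.
#' @return mean spacing in bp.
#' @examples
#' meanSnpSpacing(2512.08e6, 705243, 29) / 1000  # kb
#' @export
meanSnpSpacing <- function(spanBp, nSnps, nChromosomes = 1L) {
  stopifnot(nSnps > nChromosomes)
  spanBp / (nSnps - nChromosomes)
}
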