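#' @describeIn HaplotypeSet-class number of haplotypes (2 x samples).
#' @param x,object a `HaplotypeSet`.
#' @export
nHaplotypes <- function(x) nrow(x@alleles)

#' @describeIn HaplotypeSet-class number of variants.
#' @export
nVariants <- function(x) ncol(x@alleles)

#' @describeIn HaplotypeSet-class the haplotype x variant 0/1 matrix.
#' @export
alleleMatrix <- function(x) x@alleles

#' @describeIn HaplotypeSet-class sample identifiers.
#' @export
sampleIds <- function(x) x@sampleIds

#' @describeIn HaplotypeSet-class population label per sample.
#' @export
populations <- function(x) x@populations

#' @describeIn HaplotypeSet-class population label per haplotype row
#'   (each sample's label repeated for its two phases).
#' @export
haplotypePopulations <- function(x) rep(x@populations, each = 2L)

#' @describeIn HaplotypeSet-class the `GRanges` variant table.
#' @export
variants <- function(x) x@variants

#' @describeIn HaplotypeSet-class `TRUE` once allele 1 codes the derived
#'   state (after [polarize()]).
#' @export
isPolarized <- function(x) x@polarized

#' @describeIn HaplotypeSet-class per-sample dosage matrix (0/1/2), samples
#'   x variants, obtained by summing each sample's two phased haplotypes.
#' @export
dosageMatrix <- function(x) {
  a <- x@alleles
  d <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE] +
       a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  rownames(d) <- x@sampleIds
  d
}

#' @describeIn HaplotypeSet-class map haplotype row index to its
#'   (sample, phase) pair; returns a data.frame with columns `haplotype`,
#'   `sample`, `phase` (0 or 1).
#' @export
haplotypePairing <- function(x) {
  n <- nHaplotypes(x)
  data.frame(haplotype = seq_len(n),
             sample = x@sampleIds[(seq_len(n) + 1L) %/% 2L],
             phase = (seq_len(n) + 1L) %% 2L)
}

#' @describeIn HaplotypeSet-class subset by haplotype rows `i` and/or
#'   variant columns `j`. Row subsetting must keep haplotype pairs intact
#'   (both phases of a sample or neither).
#' @param i haplotype row indices (optional).
#' @param j variant column indices (optional).
#' @param ... ignored.
#' @param drop ignored (always `FALSE`).
#' @export
setMethod("[", "HaplotypeSet", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nHaplotypes(x))
  if (missing(j)) j <- seq_len(nVariants(x))
  i <- seq_len(nHaplotypes(x))[i]
  j <- seq_len(nVariants(x))[j]
  samp <- (i + 1L) %/% 2L
  usamp <- unique(samp)
  if (!all(tabulate(match(samp, usamp)) == 2L))
    stop("haplotype subsetting must keep both phases of each sample")
  new("HaplotypeSet",
      alleles = x@alleles[i, j, drop = FALSE],
      sampleIds = x@sampleIds[usamp],
      populations = x@populations[usamp],
      variants = x@variants[j],
      polarized = x@polarized)
})

#' @describeIn HaplotypeSet-class display a compact summary.
#' @export
setMethod("show", "HaplotypeSet", function(object) {
  pops <- table(object@populations)
  cat(sprintf("HaplotypeSet: %d haplotypes (%d samples), %d variants%s\n",
              nHaplotypes(object), length(object@sampleIds),
              nVariants(object),
              if (object@polarized) ", polarized (1 = derived)" else ""))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s (%d)", names(pops), pops), collapse = ", ")))
  chs <- runValue(seqnames(object@variants))
  cat(sprintf("  chromosomes: %s\n", paste(as.character(chs), collapse = ", ")))
})

#' @describeIn EhhProfile-class display a compact summary.
#' @param object an `EhhProfile`.
#' @export
setMethod("show", "EhhProfile", function(object) {
  cat(sprintf(
    "EhhProfile: core %d (%s allele), %d carriers, %d eval points, stop L=%s R=%s\n",
    object@coreIndex, object@allele, object@nCarriers,
    length(object@positions), object@stopReason[1], object@stopReason[2]))
})
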