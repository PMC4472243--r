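#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors Rle runValue
NULL

#' HaplotypeSet: phased haplotypes with a variant table
#'
#' The central container of the package: a binary allele matrix over phased
#' haplotypes (rows) and biallelic variants (columns), together with sample
#' identifiers, a population label per sample, and a [GenomicRanges::GRanges]
#' variant table carrying per-variant metadata (`ref`, `alt`, `ancestral`,
#' `derivedFreq`, optionally `callRate`).
#'
#' Haplotype row `i` belongs to sample `ceiling(i/2)` with phase
#' `(i - 1) %% 2` (two haplotypes per diploid sample, stored consecutively).
#' Before [polarize()] the matrix is reference-coded (1 = alternate allele);
#' after polarization 1 = derived allele and `derivedFreq` is populated.
#'
#' @slot alleles integer matrix, haplotypes x variants, entries 0/1, no
#'   missing values (completeness is a precondition of every downstream
#'   statistic; phasing/imputation are upstream of this package).
#' @slot sampleIds character vector of sample identifiers.
#' @slot populations character vector, one population label per sample.
#' @slot variants `GRanges`, one range (width 1, 1-based) per variant, in
#'   the same column order as `alleles`.
#' @slot polarized logical scalar; `TRUE` once 1 codes the derived allele.
#'
#' @seealso [HaplotypeSet()] for construction, [readPhasedVcf()] for
#'   ingestion, [applyQc()], [polarize()].
#' @export
setClass("HaplotypeSet",
  representation(
    alleles = "matrix",
    sampleIds = "character",
    populations = "character",
    variants = "GRanges",
    polarized = "logical"
  )
)

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  a <- object@alleles
  if (!is.numeric(a) && !is.integer(a))
    msg <- c(msg, "allele matrix must be numeric")
  if (anyNA(a))
    msg <- c(msg, "allele matrix contains missing values")
  else if (length(a) && !all(a == 0L | a == 1L))
    msg <- c(msg, "allele matrix entries must all be 0 or 1")
  if (nrow(a) != 2L * length(object@sampleIds))
    msg <- c(msg, sprintf(
      "haplotype count (%d) must be 2 x sample count (%d)",
      nrow(a), length(object@sampleIds)))
  if (length(object@populations) != length(object@sampleIds))
    msg <- c(msg, "need exactly one population label per sample")
  if (anyNA(object@populations))
    msg <- c(msg, "population labels must not be missing")
  if (ncol(a) != length(object@variants))
    msg <- c(msg, sprintf(
      "variant table rows (%d) must equal allele matrix columns (%d)",
      length(object@variants), ncol(a)))
  if (length(object@variants)) {
    ch <- as.character(seqnames(object@variants))
    ps <- start(object@variants)
    if (is.unsorted(order(ch, ps)) ||
        any(tapply(ps, ch, function(p) any(diff(p) <= 0)), na.rm = TRUE))
      msg <- c(msg, "variant positions must be strictly increasing within chromosome")
  }
  if (length(object@polarized) != 1L || is.na(object@polarized))
    msg <- c(msg, "'polarized' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypeSet
#'
#' @param alleles haplotypes x variants 0/1 matrix (2 rows per sample,
#'   consecutive).
#' @param sampleIds character vector of sample ids.
#' @param populations population label per sample; either a vector parallel
#'   to `sampleIds` or a named vector/map keyed by sample id.
#' @param variants `GRanges` of width-1 variant positions with at least
#'   `ref` and `alt` metadata columns; `ancestral`, `derivedFreq`,
#'   `callRate` are added as `NA` when absent.
#' @param polarized logical; is 1 already the derived allele?
#' @return A [HaplotypeSet-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1),
#'                              ref = c("A", "C"), alt = c("G", "T"))
#' hs <- HaplotypeSet(matrix(c(0L, 1L, 1L, 0L, 0L, 0L, 1L, 1L), nrow = 4),
#'                    sampleIds = c("s1", "s2"),
#'                    populations = c(s1 = "A", s2 = "B"), variants = gr)
#' hs
#' @export
HaplotypeSet <- function(alleles, sampleIds, populations, variants,
                         polarized = FALSE) {
  storage.mode(alleles) <- "integer"
  if (!is.null(names(populations)) && all(sampleIds %in% names(populations)))
    populations <- unname(populations[sampleIds])
  populations <- as.character(populations)
  for (col in c("ancestral", "derivedFreq", "callRate")) {
    if (!col %in% names(mcols(variants)))
      mcols(variants)[[col]] <- if (col == "ancestral") NA_character_ else NA_real_
  }
  new("HaplotypeSet", alleles = alleles, sampleIds = as.character(sampleIds),
      populations = populations, variants = variants, polarized = polarized)
}

#' EhhProfile: EHH decay around a core variant for one allele
#'
#' Extended haplotype homozygosity (EHH) evaluated at successive markers on
#' both flanks of a core variant, for the haplotypes carrying one core
#' allele. EHH at position `m` is the probability that two distinct carrier
#' haplotypes are identical at every marker between the core and `m`
#' (inclusive), estimated as `sum_g C(n_g,2) / C(n_c,2)` over groups `g` of
#' carriers sharing the stretch. By construction EHH = 1 at the core and is
#' non-increasing outward on each flank.
#'
#' @slot coreIndex integer index of the core variant.
#' @slot corePosition bp position of the core variant.
#' @slot allele `"ancestral"` or `"derived"` (or `"alt"`/`"ref"` before
#'   polarization).
#' @slot positions integer bp positions at which EHH was evaluated, sorted
#'   ascending; the core position is included with EHH 1.
#' @slot ehh numeric EHH values aligned to `positions`.
#' @slot stopReason character of length 2, stop cause per flank
#'   (`c(left, right)`): `"floor"` (decayed below the floor), `"edge"`
#'   (chromosome end reached first) or `"gap"` (inter-marker gap exceeded
#'   the maximum).
#' @slot nCarriers integer count of carrier haplotypes.
#' @export
setClass("EhhProfile",
  representation(
    coreIndex = "integer",
    corePosition = "integer",
    allele = "character",
    positions = "integer",
    ehh = "numeric",
    stopReason = "character",
    nCarriers = "integer"
  )
)

setValidity("EhhProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@ehh))
    msg <- c(msg, "positions and ehh must be parallel")
  if (is.unsorted(object@positions, strictly = TRUE))
    msg <- c(msg, "evaluation positions must be strictly increasing")
  if (length(object@ehh) && (min(object@ehh) < 0 || max(object@ehh) > 1))
    msg <- c(msg, "EHH values must lie in [0, 1]")
  if (length(object@stopReason) != 2L)
    msg <- c(msg, "stopReason must give a cause per flank (left, right)")
  if (length(msg)) msg else TRUE
})
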