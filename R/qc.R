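#' Quality-control filtering of a haplotype panel
#'
#' Removes variants failing any of three per-variant filters, in order:
#' call rate below a threshold (pre-imputation call rate supplied via the
#' `callRate` variant column), monomorphic across all haplotypes of all
#' populations, and Mendelian inconsistency in at least one supplied trio
#' (a child genotype impossible given its parents' genotypes). Each variant
#' is attributed to the first filter it fails, so the report's removal
#' counts always sum back to the input count.
#'
#' @param x a [HaplotypeSet-class].
#' @param minCallRate minimum call rate to retain (e.g. 0.90); `NULL`
#'   disables the filter. Requires the `callRate` variant column.
#' @param dropMonomorphic drop variants with the same allele on every
#'   haplotype?
#' @param trios optional data.frame (`child`, `sire`, `dam` sample ids) or
#'   TSV path; any trio with an impossible genotype configuration removes
#'   the variant.
#' @return list with elements `haplotypes` (filtered `HaplotypeSet`) and
#'   `report` (a [qcReport()] count list).
#' @examples
#' hs <- simulateNeutral(simConfig(seed = 1, nPopulations = 2,
#'   haplotypesPerPopulation = 10, chromLength = 1e5))$haplotypes
#' applyQc(hs)$report
#' @export
applyQc <- function(x, minCallRate = NULL, dropMonomorphic = TRUE,
                    trios = NULL) {
  m <- nVariants(x)
  fail <- integer(m)  # 0 = keep, 1 = callrate, 2 = monomorphic, 3 = mendelian

  if (!is.null(minCallRate)) {
    cr <- mcols(variants(x))$callRate
    if (all(is.na(cr)))
      stop("minCallRate given but the variant table has no call rates")
    fail[!is.na(cr) & cr < minCallRate] <- 1L
  }

  if (dropMonomorphic) {
    cs <- colSums(alleleMatrix(x))
    mono <- cs == 0L | cs == nHaplotypes(x)
    fail[fail == 0L & mono] <- 2L
  }

  if (!is.null(trios)) {
    if (is.character(trios)) trios <- readTrios(trios)
    bad <- mendelianInconsistent(x, trios)
    fail[fail == 0L & bad] <- 3L
  }

  keep <- fail == 0L
  if (!any(keep)) stop("empty panel: every variant removed by QC")
  report <- qcReport(
    n_input = m,
    n_removed_callrate = sum(fail == 1L),
    n_removed_monomorphic = sum(fail == 2L),
    n_removed_mendelian = sum(fail == 3L),
    n_removed_unpolarized = 0L,
    n_retained = sum(keep))
  list(haplotypes = x[, keep], report = report)
}

#' Assemble and validate a QC count report
#'
#' @param n_input,n_removed_callrate,n_removed_monomorphic,n_removed_mendelian,n_removed_unpolarized,n_retained
#'   integer counts; removals plus retained must reconcile to the input.
#' @return a named list of the six counts (class `"qcReport"`).
#' @export
qcReport <- function(n_input, n_removed_callrate = 0L,
                     n_removed_monomorphic = 0L, n_removed_mendelian = 0L,
                     n_removed_unpolarized = 0L, n_retained = n_input) {
  r <- list(n_input = as.integer(n_input),
            n_removed_callrate = as.integer(n_removed_callrate),
            n_removed_monomorphic = as.integer(n_removed_monomorphic),
            n_removed_mendelian = as.integer(n_removed_mendelian),
            n_removed_unpolarized = as.integer(n_removed_unpolarized),
            n_retained = as.integer(n_retained))
  if (r$n_input != r$n_retained + r$n_removed_callrate +
      r$n_removed_monomorphic + r$n_removed_mendelian + r$n_removed_unpolarized)
    stop("QC counts do not reconcile to n_input")
  structure(r, class = "qcReport")
}

#' @rdname qcReport
#' @param x a `qcReport`.
#' @param ... ignored.
#' @method print qcReport
#' @export
print.qcReport <- function(x, ...) {
  cat("QC report:\n")
  for (nm in names(x)) cat(sprintf("  %-24s %d\n", nm, x[[nm]]))
  invisible(x)
}

# Variant-level Mendelian check on dosages: a variant is inconsistent if any
# trio shows an impossible configuration for biallelic inheritance.
mendelianInconsistent <- function(x, trios) {
  d <- dosageMatrix(x)
  bad <- logical(nVariants(x))
  for (k in seq_len(nrow(trios))) {
    ci <- match(trios$child[k], sampleIds(x))
    si <- match(trios$sire[k], sampleIds(x))
    di <- match(trios$dam[k], sampleIds(x))
    if (anyNA(c(ci, si, di)))
      stop("trio row ", k, " names a sample not in the panel")
    ch <- d[ci, ]; sr <- d[si, ]; dm <- d[di, ]
    bad <- bad |
      (ch == 2L & (sr == 0L | dm == 0L)) |
      (ch == 0L & (sr == 2L | dm == 2L)) |
      (ch == 1L & ((sr == 0L & dm == 0L) | (sr == 2L & dm == 2L)))
  }
  bad
}

#' Polarize alleles to ancestral/derived coding
#'
#' Flips the allele coding of each variant so that 1 codes the derived
#' allele, using an ancestral-allele table keyed by (chrom, pos). Where the
#' ancestral base equals the ALT allele the column is bit-flipped and
#' REF/ALT swapped; where it equals REF the coding is unchanged. Variants
#' whose ancestral base is unknown, absent from the table, or matches
#' neither allele are dropped (counted in the report, never fatal).
#' `derivedFreq` is populated for every retained variant.
#'
#' @param x a [HaplotypeSet-class].
#' @param ancestral data.frame (`chrom`, `pos`, `ancestral`) or TSV path.
#' @return list with `haplotypes` (polarized `HaplotypeSet`) and `report`
#'   (a [qcReport()] whose `n_removed_unpolarized` counts the drops).
#' @export
polarize <- function(x, ancestral) {
  if (is.character(ancestral)) ancestral <- readAncestralTable(ancestral)
  gr <- variants(x)
  key <- paste(as.character(seqnames(gr)), start(gr))
  anc <- ancestral$ancestral[match(key, paste(ancestral$chrom, ancestral$pos))]
  ref <- mcols(gr)$ref; alt <- mcols(gr)$alt
  isRef <- !is.na(anc) & anc == ref
  isAlt <- !is.na(anc) & anc == alt
  keep <- isRef | isAlt
  if (!any(keep)) stop("empty panel: no variant could be polarized")

  a <- alleleMatrix(x)
  flip <- which(isAlt)
  a[, flip] <- 1L - a[, flip]
  mcols(gr)$ancestral <- anc
  tmp <- mcols(gr)$ref[flip]
  mcols(gr)$ref[flip] <- mcols(gr)$alt[flip]  # after flip, ref slot = ancestral
  mcols(gr)$alt[flip] <- tmp
  mcols(gr)$derivedFreq <- colMeans(a)

  out <- HaplotypeSet(a[, keep, drop = FALSE], sampleIds(x),
                      populations(x), gr[keep], polarized = TRUE)
  report <- qcReport(n_input = nVariants(x),
                     n_removed_unpolarized = sum(!keep),
                     n_retained = sum(keep))
  list(haplotypes = out, report = report)
}
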