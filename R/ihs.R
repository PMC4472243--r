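#' Genome-wide iHS scan
#'
#' Computes, for every eligible variant of a polarized panel, the integrated
#' EHH areas of the ancestral and derived core alleles (`ihh_a`, `ihh_d`)
#' and the raw score `ln(ihh_a / ihh_d)`. A variant is eligible when its
#' minor allele frequency is at least `mafMin` (the statistic is unstable at
#' extreme frequencies and has maximal power at intermediate ones) and both
#' alleles have at least two carriers. Flanks truncated by a chromosome end
#' before decaying to `decayFloor` make the record invalid (reason
#' `"edge"`, configurable), as do oversized inter-marker gaps (`"gap"`).
#'
#' The scan runs in compiled code; [computeEhh()] + [integrateIhh()] are the
#' equivalent reference path for a single core.
#'
#' @param x a polarized [HaplotypeSet-class] (see [polarize()]).
#' @param decayFloor EHH decay/integration floor (default 0.05).
#' @param maxGap maximum inter-marker gap in bp (default 200 kb).
#' @param mafMin minor-allele-frequency floor for cores (default 0.05).
#' @param edgeRule `"invalid"` (default) or `"integrate"` for edge-truncated
#'   flanks.
#' @return data.frame with one row per variant: `chrom`, `pos`,
#'   `derived_freq`, `ihh_a`, `ihh_d`, `raw` (`ln(ihh_a/ihh_d)`), `valid`,
#'   `reason` (`"ok"`, `"maf"`, `"carriers"`, `"edge"`, `"gap"`). Columns
#'   `ihs`, `p_two_sided`, `p_ihs` are added by [standardizeIhs()] and
#'   [ihsPvalues()].
#' @examples
#' sim <- simulateNeutral(simConfig(seed = 5, nPopulations = 1,
#'   haplotypesPerPopulation = 40, chromLength = 2e6))
#' pol <- polarize(sim$haplotypes, sim$ancestral)$haplotypes
#' head(ihsScan(pol))
#' @export
ihsScan <- function(x, decayFloor = 0.05, maxGap = 2e5, mafMin = 0.05,
                    edgeRule = c("invalid", "integrate")) {
  edgeRule <- match.arg(edgeRule)
  if (!isPolarized(x))
    stop("panel must be polarized (1 = derived allele) before an iHS scan")
  gr <- variants(x)
  freq <- mcols(gr)$derivedFreq
  maf <- pmin(freq, 1 - freq)
  doCore <- maf >= mafMin
  chromId <- as.integer(factor(as.character(seqnames(gr)),
                               levels = unique(as.character(seqnames(gr)))))
  res <- ihh_scan_cpp(alleleMatrix(x), start(gr), chromId, doCore,
                      decayFloor, maxGap, edgeRule == "integrate")
  reasonMap <- c("ok", "carriers", "edge", "gap")
  reason <- ifelse(!doCore, "maf",
                   reasonMap[pmax(res$reason_a, res$reason_d) + 1L])
  raw <- ifelse(!is.na(res$ihh_a) & !is.na(res$ihh_d) &
                res$ihh_a > 0 & res$ihh_d > 0,
                log(res$ihh_a / res$ihh_d), NA_real_)
  valid <- reason == "ok" & !is.na(raw)
  reason[reason == "ok" & !valid] <- "zero_area"
  data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
             derived_freq = freq, ihh_a = res$ihh_a, ihh_d = res$ihh_d,
             raw = raw, valid = valid, reason = reason,
             stringsAsFactors = FALSE)
}

#' Raw (unstandardized) iHS
#'
#' `ln(ihh_a / ihh_d)`: positive when haplotypes around the ancestral allele
#' are longer, negative when the derived allele carries the long haplotypes
#' (the hard-sweep signature on a derived allele).
#'
#' @param ihh_a,ihh_d integrated EHH areas (bp) for the ancestral and
#'   derived core alleles; both must be positive for a defined score.
#' @return numeric; `NA` where either area is missing or non-positive.
#' @export
rawIhs <- function(ihh_a, ihh_d) {
  ifelse(!is.na(ihh_a) & !is.na(ihh_d) & ihh_a > 0 & ihh_d > 0,
         log(ihh_a / ihh_d), NA_real_)
}

#' Standardize raw iHS within derived-allele-frequency bins
#'
#' Raw `ln(ihh_a/ihh_d)` has a frequency-dependent distribution, so scores
#' are standardized within bins of derived allele frequency:
#' `ihs = (raw - mean_bin) / sd_bin`. Bins of width `1/nBins` partition
#' (0, 1); bins holding fewer than `minPerBin` valid records are merged with
#' their nearest neighbour until all used bins are adequately filled. After
#' standardization the scores are approximately standard normal under
#' neutrality, which licenses the Gaussian p-value transform of
#' [ihsPvalues()].
#'
#' @param records data.frame from [ihsScan()] (needs `raw`, `derived_freq`,
#'   `valid`).
#' @param nBins number of equal-width frequency bins (default 40, i.e.
#'   width 0.025).
#' @param minPerBin minimum valid records per bin before merging
#'   (default 50).
#' @return list with `records` (input plus `ihs` column) and `bins`
#'   (data.frame `lower`, `upper`, `n`, `mean`, `sd` per merged bin).
#' @export
standardizeIhs <- function(records, nBins = 40L, minPerBin = 50L) {
  ok <- records$valid & !is.na(records$raw)
  if (!any(ok)) stop("no valid raw iHS records to standardize")
  edges <- seq(0, 1, length.out = nBins + 1L)
  bin <- findInterval(records$derived_freq, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)

  # merge underfilled bins with their nearest (by index) occupied neighbour
  cnt <- tabulate(bin[ok], nbins = nBins)
  grp <- seq_len(nBins)
  repeat {
    gcnt <- vapply(split(cnt, grp), sum, numeric(1))
    small <- names(gcnt)[gcnt > 0 & gcnt < minPerBin]
    if (!length(small) || length(unique(grp[cnt > 0 | TRUE])) <= 1L) break
    g <- as.integer(small[1])
    others <- setdiff(unique(grp), g)
    if (!length(others)) break
    # nearest neighbouring group by bin-index distance
    dist <- vapply(others, function(o)
      min(abs(outer(which(grp == o), which(grp == g), "-"))), numeric(1))
    grp[grp == g] <- others[which.min(dist)]
    if (length(unique(grp)) == 1L) break
  }

  gid <- grp[bin]
  mu <- tapply(records$raw[ok], gid[ok], mean)
  sdv <- tapply(records$raw[ok], gid[ok], stats::sd)
  if (any(!is.na(sdv) & sdv == 0) || all(is.na(sdv)))
    stop("degenerate standardization bin with zero spread")
  records$ihs <- NA_real_
  gi <- as.character(gid)
  records$ihs[ok] <- (records$raw[ok] - mu[gi[ok]]) / sdv[gi[ok]]

  usedGroups <- sort(unique(grp[tabulate(bin[ok], nbins = nBins) > 0]))
  bins <- do.call(rbind, lapply(usedGroups, function(g) {
    bidx <- which(grp == g)
    data.frame(lower = edges[min(bidx)], upper = edges[max(bidx) + 1L],
               n = sum(gid[ok] == g),
               mean = unname(mu[as.character(g)]),
               sd = unname(sdv[as.character(g)]))
  }))
  list(records = records, bins = bins)
}

#' Two-sided Gaussian p-values for standardized iHS
#'
#' Under neutrality the standardized score is standard normal, so the
#' two-sided p-value is `p = 2 * (1 - Phi(|ihs|))` (equivalently
#' `1 - 2|Phi(ihs) - 0.5|`); `p_ihs = -log10(p)` is its display transform.
#'
#' @param records data.frame with an `ihs` column (from [standardizeIhs()]),
#'   or a bare numeric vector of standardized scores.
#' @return the records with `p_two_sided` and `p_ihs` columns added (or,
#'   for numeric input, a data.frame of `ihs`, `p_two_sided`, `p_ihs`).
#' @examples
#' ihsPvalues(c(0, 2, 7))
#' @export
ihsPvalues <- function(records) {
  if (is.numeric(records)) records <- data.frame(ihs = records)
  p <- 2 * stats::pnorm(abs(records$ihs), lower.tail = FALSE)
  records$p_two_sided <- p
  records$p_ihs <- -log10(p)
  records
}
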