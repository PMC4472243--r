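#' Extended haplotype homozygosity around a core variant
#'
#' Computes the EHH decay profile for the haplotypes carrying one allele of
#' a core variant. At a flanking marker `m`, carriers are partitioned into
#' groups identical at every marker from the core through `m`, and
#' `EHH(m) = sum_g C(n_g, 2) / C(n_c, 2)` with `n_c` the carrier count.
#' EHH equals 1 at the core and is non-increasing outward. Evaluation on a
#' flank stops as soon as EHH falls below `decayFloor` (the sub-floor value
#' is recorded), the chromosome ends, or an inter-marker gap exceeds
#' `maxGap`; the per-flank stop cause is recorded.
#'
#' This is the readable single-core reference path; the genome-wide scan in
#' [ihsScan()] uses a compiled implementation of the same definitions.
#'
#' @param x a [HaplotypeSet-class].
#' @param core variant column index of the core.
#' @param allele which core allele's carriers to follow: `"derived"`
#'   (allele 1, requires polarization) or `"ancestral"` (allele 0).
#' @param decayFloor EHH level below which a flank stops (default 0.05).
#' @param maxGap maximum tolerated distance between adjacent evaluated
#'   markers, bp (default 200 kb).
#' @return An [EhhProfile-class].
#' @examples
#' hs <- simulateNeutral(simConfig(seed = 3, nPopulations = 1,
#'   haplotypesPerPopulation = 20, chromLength = 5e5))$haplotypes
#' computeEhh(hs, core = 10, allele = "ancestral")
#' @export
computeEhh <- function(x, core, allele = c("derived", "ancestral"),
                       decayFloor = 0.05, maxGap = 2e5) {
  allele <- match.arg(allele)
  a <- alleleMatrix(x)
  stopifnot(core >= 1, core <= ncol(a))
  target <- if (allele == "derived") 1L else 0L
  carriers <- which(a[, core] == target)
  if (length(carriers) < 2L)
    stop("allele not scorable: fewer than 2 carrier haplotypes at core ", core)

  gr <- variants(x)
  ch <- as.character(seqnames(gr))
  onChrom <- which(ch == ch[core])
  pos <- start(gr)

  flank <- function(dir) {
    lim <- if (dir < 0) min(onChrom) else max(onChrom)
    gid <- rep(1L, length(carriers))
    ehh <- numeric(0); p <- integer(0)
    prevPos <- pos[core]; cur <- 1
    m <- core + dir
    while (if (dir < 0) m >= lim else m <= lim) {
      if (abs(pos[m] - prevPos) > maxGap)
        return(list(ehh = ehh, pos = p, reason = "gap"))
      gid <- match(paste(gid, a[carriers, m]), unique(paste(gid, a[carriers, m])))
      ng <- tabulate(gid)
      cur <- sum(choose(ng, 2)) / choose(length(carriers), 2)
      ehh <- c(ehh, cur); p <- c(p, pos[m])
      if (cur < decayFloor)
        return(list(ehh = ehh, pos = p, reason = "floor"))
      prevPos <- pos[m]
      m <- m + dir
    }
    list(ehh = ehh, pos = p, reason = "edge")
  }

  L <- flank(-1L); R <- flank(+1L)
  new("EhhProfile",
      coreIndex = as.integer(core),
      corePosition = as.integer(pos[core]),
      allele = allele,
      positions = as.integer(c(rev(L$pos), pos[core], R$pos)),
      ehh = c(rev(L$ehh), 1, R$ehh),
      stopReason = c(L$reason, R$reason),
      nCarriers = length(carriers))
}

#' Integrate an EHH profile into iHH (bp-scaled area)
#'
#' Trapezoidal area under the EHH-versus-position curve over both flanks,
#' keeping only the portion with `EHH >= decayFloor` and closing each flank
#' by linear interpolation to the floor crossing. A flank that ran into a
#' chromosome end before decaying to the floor yields an invalid area
#' (reason `"edge"`) unless `edgeRule = "integrate"`, since the truncated
#' area would be biased downward; a flank stopped by an oversized gap is
#' always invalid (reason `"gap"`).
#'
#' @param profile an [EhhProfile-class] computed with the same `decayFloor`.
#' @param decayFloor integration floor (default 0.05).
#' @param edgeRule `"invalid"` (default) or `"integrate"` for edge-truncated
#'   profiles.
#' @return list with `ihh` (bp area, `NA` when invalid), `valid` (logical)
#'   and `reason` (`"ok"`, `"edge"` or `"gap"`).
#' @export
integrateIhh <- function(profile, decayFloor = 0.05,
                         edgeRule = c("invalid", "integrate")) {
  edgeRule <- match.arg(edgeRule)
  bad <- if (edgeRule == "invalid") c("edge", "gap") else "gap"
  if (any(profile@stopReason %in% bad)) {
    reason <- if ("gap" %in% profile@stopReason) "gap" else "edge"
    return(list(ihh = NA_real_, valid = FALSE, reason = reason))
  }
  coreAt <- match(profile@corePosition, profile@positions)

  flankArea <- function(idx) {  # idx: outward-ordered indices incl. core
    p <- profile@positions[idx]; e <- profile@ehh[idx]
    area <- 0
    for (k in seq_along(idx)[-1]) {
      gap <- abs(p[k] - p[k - 1])
      if (e[k] >= decayFloor) {
        area <- area + 0.5 * (e[k - 1] + e[k]) * gap
      } else {
        dx <- gap * (e[k - 1] - decayFloor) / (e[k - 1] - e[k])
        area <- area + 0.5 * (e[k - 1] + decayFloor) * dx
        break
      }
    }
    area
  }
  n <- length(profile@positions)
  left <- flankArea(coreAt:1)
  right <- flankArea(coreAt:n)
  list(ihh = left + right, valid = TRUE, reason = "ok")
}
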