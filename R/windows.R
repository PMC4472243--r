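#' Tile the genome into fixed non-overlapping windows
#'
#' Per chromosome, windows cover `[k*w, (k+1)*w)` (0-based half-open; the
#' reported `start`/`end` columns use this convention, anchored at
#' coordinate 0) from 0 to past the last variant. Windows containing no
#' variant are dropped.
#'
#' @param x a [HaplotypeSet-class] or a `GRanges` of variant positions.
#' @param windowSize window width in bp (default 500 kb).
#' @return data.frame `chrom`, `start`, `end` (0-based half-open),
#'   `n_variants`.
#' @export
tileWindows <- function(x, windowSize = 5e5) {
  gr <- if (is(x, "HaplotypeSet")) variants(x) else x
  ch <- as.character(seqnames(gr))
  pos <- start(gr)                      # 1-based; 0-based = pos - 1
  win <- (pos - 1L) %/% as.integer(windowSize)
  key <- paste(ch, win)
  first <- !duplicated(key)
  out <- data.frame(chrom = ch[first],
                    start = win[first] * windowSize,
                    end = (win[first] + 1) * windowSize,
                    n_variants = as.integer(table(key)[key[first]]),
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Aggregate per-SNP iHS into window scores
#'
#' For each window, the mean of |iHS| over the valid standardized records it
#' contains, and the window-level two-sided Gaussian p-value
#' `p = 2 * (1 - Phi(mean |iHS|))`. Significance calling operates on these
#' window-level p-values by default; per-SNP p-values remain available from
#' [ihsPvalues()].
#'
#' @param records standardized iHS records ([standardizeIhs()]).
#' @param windows window tiling from [tileWindows()] (or `NULL` to tile
#'   from the records at `windowSize`).
#' @param windowSize used only when `windows` is `NULL` (default 500 kb).
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, `mean_abs_ihs`,
#'   `p_two_sided`, one row per window holding at least one valid record.
#' @export
scoreWindows <- function(records, windows = NULL, windowSize = 5e5) {
  ok <- records$valid & !is.na(records$ihs)
  r <- records[ok, , drop = FALSE]
  if (is.null(windows)) {
    w <- as.integer(windowSize)
  } else {
    w <- unique(windows$end - windows$start)
    if (length(w) != 1L) stop("windows must share a single width")
  }
  win <- (r$pos - 1L) %/% w
  key <- paste(r$chrom, win)
  agg <- tapply(abs(r$ihs), key, mean)
  n <- tapply(rep(1L, nrow(r)), key, sum)
  first <- !duplicated(key)
  out <- data.frame(chrom = r$chrom[first],
                    start = win[first] * w,
                    end = (win[first] + 1) * w,
                    n_snps = as.integer(n[key[first]]),
                    mean_abs_ihs = as.numeric(agg[key[first]]),
                    stringsAsFactors = FALSE)
  if (!is.null(windows)) {
    miss <- setdiff(paste(out$chrom, out$start), paste(windows$chrom, windows$start))
    if (length(miss)) stop("records fall outside the supplied tiling")
  }
  out$p_two_sided <- 2 * stats::pnorm(out$mean_abs_ihs, lower.tail = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' False-discovery-rate adjustment
#'
#' Either the standard Benjamini-Hochberg step-up (`"bh"`), or a
#' Storey-type variant (`"storey_lambda"`, the default elsewhere in the
#' package) that first estimates the null proportion from the upper tail of
#' the p-value distribution, `pi0 = min(1, #{p > lambda} / ((1 - lambda) m))`
#' with `lambda = 0.75`, and scales the BH-adjusted values by it. Using the
#' empirical p-values above the 75th-percentile cutoff to calibrate the null
#' makes the adjustment less conservative when many tests are non-null.
#'
#' @param p numeric p-values in (0, 1].
#' @param method `"storey_lambda"` or `"bh"`.
#' @param lambda tail cutoff for the null-proportion estimate (default
#'   0.75).
#' @return numeric q-values, same length and order as `p`.
#' @examples
#' fdrAdjust(c(0.01, 0.02, 0.03, 0.04), method = "bh")
#' @export
fdrAdjust <- function(p, method = c("storey_lambda", "bh"), lambda = 0.75) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey_lambda") {
    pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * length(p)))
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Call significant windows
#'
#' Adds FDR-adjusted `q` values to window scores and flags windows with
#' `q <= qThreshold`. Windows tied exactly at the threshold are all
#' included. Optionally labels runs of adjacent significant windows with a
#' shared `region` id (adjacency = same chromosome, abutting coordinates).
#'
#' @param scores window scores from [scoreWindows()].
#' @param qThreshold significance level on q (default 0.05).
#' @param method,lambda passed to [fdrAdjust()].
#' @param mergeAdjacent label adjacent significant windows as one region?
#'   (default `FALSE`).
#' @return `scores` with columns `q`, `significant` (and `region` if
#'   requested; `NA` for non-significant windows).
#' @export
callRegions <- function(scores, qThreshold = 0.05,
                        method = c("storey_lambda", "bh"), lambda = 0.75,
                        mergeAdjacent = FALSE) {
  scores$q <- fdrAdjust(scores$p_two_sided, method = method, lambda = lambda)
  scores$significant <- scores$q <= qThreshold
  if (mergeAdjacent) {
    scores <- scores[order(scores$chrom, scores$start), , drop = FALSE]
    newRegion <- scores$significant &
      !(c(FALSE, scores$significant[-nrow(scores)]) &
        c(FALSE, scores$chrom[-nrow(scores)] == scores$chrom[-1] &
                 scores$end[-nrow(scores)] == scores$start[-1]))
    scores$region <- ifelse(scores$significant, cumsum(newRegion), NA_integer_)
  }
  scores
}

#' Pairwise overlap of significant windows across populations
#'
#' Counts, for every pair of populations, the windows significant in both.
#' All populations must have been scored on the identical tiling. The
#' diagonal holds each population's significant-window count. The windows
#' significant in every population are also returned.
#'
#' @param callsByPop named list of called window data.frames
#'   ([callRegions()]), one per population.
#' @return list with `counts` (symmetric integer matrix) and `commonAll`
#'   (data.frame of windows significant in all populations).
#' @export
crossPopulationOverlap <- function(callsByPop) {
  stopifnot(is.list(callsByPop), length(callsByPop) >= 2,
            !is.null(names(callsByPop)))
  keys <- lapply(callsByPop, function(d) paste(d$chrom, d$start, d$end))
  tiling <- keys[[1]]
  for (k in keys[-1])
    if (length(k) != length(tiling) || any(sort(k) != sort(tiling)))
      stop("populations were scored on different window tilings")
  sig <- lapply(callsByPop, function(d) paste(d$chrom, d$start, d$end)[d$significant])
  pops <- names(callsByPop)
  n <- length(pops)
  counts <- matrix(0L, n, n, dimnames = list(pops, pops))
  for (i in seq_len(n)) for (j in seq_len(n))
    counts[i, j] <- length(intersect(sig[[i]], sig[[j]]))
  allKey <- Reduce(intersect, sig)
  d1 <- callsByPop[[1]]
  commonAll <- d1[paste(d1$chrom, d1$start, d1$end) %in% allKey,
                  c("chrom", "start", "end"), drop = FALSE]
  list(counts = counts, commonAll = commonAll)
}

#' Write significant windows as BED
#'
#' @param scores called window scores ([callRegions()]).
#' @param path output BED path (0-based half-open, as BED requires).
#' @return `path`, invisibly.
#' @export
writeSignificantBed <- function(scores, path) {
  sig <- scores[scores$significant, , drop = FALSE]
  lines <- sprintf("%s\t%d\t%d\t%s\t%g", sig$chrom, as.integer(sig$start),
                   as.integer(sig$end),
                   sprintf("w_%s_%d", sig$chrom, as.integer(sig$start)),
                   sig$q)
  writeLines(lines, path)
  invisible(path)
}
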