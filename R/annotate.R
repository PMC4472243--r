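#' Genes overlapping significant windows
#'
#' A gene is reported when it overlaps a significant window by at least one
#' base (any-overlap rule); a gene touching several significant windows is
#' counted once. Window coordinates are the package's 0-based half-open
#' convention; genes are the 1-based closed `GRanges` convention from
#' [readGenes()] — the conversion happens here, at the boundary.
#'
#' @param windows called window scores ([callRegions()]); only rows with
#'   `significant == TRUE` are used (or pass a pre-filtered data.frame
#'   without a `significant` column).
#' @param genes `GRanges` of gene models ([readGenes()]).
#' @return sorted character vector of `gene_id`s.
#' @export
genesInWindows <- function(windows, genes) {
  if (!is.null(windows$significant))
    windows <- windows[windows$significant, , drop = FALSE]
  if (!nrow(windows)) return(character(0))
  wgr <- GRanges(windows$chrom,
                 IRanges(windows$start + 1L, windows$end))  # half-open -> closed
  hits <- GenomicRanges::findOverlaps(genes, wgr, ignore.strand = TRUE)
  sort(unique(mcols(genes)$gene_id[S4Vectors::queryHits(hits)]))
}

#' Genes containing top-FST SNPs
#'
#' Strict containment: a SNP position must lie within the gene span
#' (boundaries included). Returns the genes and per-gene SNP counts.
#'
#' @param records FST records with a `top` column ([callTopFraction()]);
#'   only `top == TRUE` rows are used.
#' @param genes `GRanges` of gene models ([readGenes()]).
#' @return data.frame `gene_id`, `n_top_snps`, sorted by `gene_id`.
#' @export
genesWithTopSnps <- function(records, genes) {
  top <- records[records$top, , drop = FALSE]
  if (!nrow(top))
    return(data.frame(gene_id = character(0), n_top_snps = integer(0)))
  sgr <- GRanges(top$chrom, IRanges(top$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(sgr, genes, type = "within",
                                      ignore.strand = TRUE)
  ids <- mcols(genes)$gene_id[S4Vectors::subjectHits(hits)]
  if (!length(ids))
    return(data.frame(gene_id = character(0), n_top_snps = integer(0)))
  tab <- table(ids)
  data.frame(gene_id = names(tab), n_top_snps = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Intersect the gene hits of the two scan methods
#'
#' Genes flagged by both the within-population iHS windows and the
#' across-population top-FST SNPs are the strongest selection-signature
#' candidates; the intersection is reported per population.
#'
#' @param ihsGenes character vector of gene ids from [genesInWindows()].
#' @param fstGenes character vector of gene ids (e.g.
#'   `genesWithTopSnps(...)$gene_id`).
#' @param population population label carried through to the result.
#' @return list with `population`, `genes_ihs`, `genes_fst`, `genes_both`
#'   (sorted intersection).
#' @export
intersectMethods <- function(ihsGenes, fstGenes, population = NA_character_) {
  list(population = population,
       genes_ihs = sort(unique(ihsGenes)),
       genes_fst = sort(unique(fstGenes)),
       genes_both = sort(intersect(ihsGenes, fstGenes)))
}
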