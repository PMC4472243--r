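#' Read a phased VCF into a HaplotypeSet
#'
#' Ingests a VCF of phased, complete, biallelic SNP genotypes together with
#' a sample-to-population map. Genotypes must be phased (`|` separator) and
#' complete: the panels this package analyses are assumed imputed and phased
#' upstream, so any missing (`./.`) or unphased (`0/1`) genotype is an
#' ingestion error naming the first offending record. Records that are not
#' biallelic SNPs (multi-allelic ALT, indels) are skipped with a warning and
#' a count.
#'
#' @param path path to a VCF (plain or gzipped).
#' @param popMap either a data.frame with columns `sample_id` and
#'   `population`, or the path to a two-column TSV of the same layout.
#' @return A [HaplotypeSet-class]; its variant table carries `ref`, `alt`
#'   and (if an `CR` INFO-free `callRate` cannot be known) `callRate = NA`.
#'   The attribute `nSkipped` records non-biallelic-SNP records dropped.
#' @seealso [writePhasedVcf()], [applyQc()], [polarize()]
#' @export
readPhasedVcf <- function(path, popMap) {
  if (is.character(popMap)) popMap <- readPopulationMap(popMap)
  stopifnot(all(c("sample_id", "population") %in% names(popMap)))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  nSkipped <- sum(!keep)
  if (nSkipped > 0)
    warning(sprintf("skipped %d record(s) that are not biallelic SNPs", nSkipped))
  if (!any(keep)) stop("no biallelic SNP records in ", path)

  gt <- v@gt[keep, -1L, drop = FALSE]  # drop FORMAT column
  fmt <- v@gt[keep, 1L]
  gtIdx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                  function(f) match("GT", f), integer(1))
  if (anyNA(gtIdx)) stop("VCF record without GT field")
  if (any(gtIdx != 1L)) {
    gt <- matrix(vapply(seq_along(gt), function(k) {
      strsplit(gt[k], ":", fixed = TRUE)[[1]][gtIdx[(k - 1L) %% nrow(gt) + 1L]]
    }, character(1)), nrow = nrow(gt))
  } else {
    gt <- sub(":.*$", "", gt)
  }
  sampleIds <- colnames(v@gt)[-1L]

  bad <- which(!grepl("^[01]\\|[01]$", gt))
  if (length(bad)) {
    k <- bad[1]
    rec <- (k - 1L) %% nrow(gt) + 1L
    smp <- sampleIds[(k - 1L) %/% nrow(gt) + 1L]
    stop(sprintf(
      "unphased or missing genotype '%s' at %s:%s (sample %s); input must be phased and complete",
      gt[k], fix[keep, "CHROM"][rec], fix[keep, "POS"][rec], smp))
  }

  # haplotype rows: sample 1 phase 0, sample 1 phase 1, sample 2 phase 0, ...
  h0 <- substr(gt, 1L, 1L) == "1"
  h1 <- substr(gt, 3L, 3L) == "1"
  nvar <- nrow(gt); nsmp <- length(sampleIds)
  alleles <- matrix(0L, nrow = 2L * nsmp, ncol = nvar)
  alleles[seq(1L, 2L * nsmp, by = 2L), ] <- t(matrix(as.integer(h0), nvar, nsmp))
  alleles[seq(2L, 2L * nsmp, by = 2L), ] <- t(matrix(as.integer(h1), nvar, nsmp))

  miss <- setdiff(sampleIds, popMap$sample_id)
  if (length(miss))
    stop("samples missing from population map: ", paste(miss, collapse = ", "))
  pops <- popMap$population[match(sampleIds, popMap$sample_id)]

  gr <- GRanges(fix[keep, "CHROM"],
                IRanges(as.integer(fix[keep, "POS"]), width = 1L),
                ref = unname(ref[keep]), alt = unname(alt[keep]))
  ord <- order(as.character(seqnames(gr)), start(gr))
  gr <- gr[ord]
  alleles <- alleles[, ord, drop = FALSE]
  hs <- HaplotypeSet(alleles, sampleIds, pops, gr)
  attr(hs, "nSkipped") <- nSkipped
  hs
}

#' Write a HaplotypeSet as a phased VCF
#'
#' Emits a minimal VCFv4.2 with phased `GT` fields, suitable for
#' round-tripping through [readPhasedVcf()].
#'
#' @param x a [HaplotypeSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhasedVcf <- function(x, path) {
  gr <- variants(x)
  chroms <- unique(as.character(seqnames(gr)))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", chroms),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleIds(x)), collapse = "\t"))
  a <- alleleMatrix(x)
  h0 <- t(a[seq(1L, nrow(a), by = 2L), , drop = FALSE])  # variants x samples
  h1 <- t(a[seq(2L, nrow(a), by = 2L), , drop = FALSE])
  gt <- matrix(paste0(h0, "|", h1), nrow = nrow(h0))
  body <- paste(as.character(seqnames(gr)), start(gr),
                sprintf("snp%d", seq_along(gr)),
                mcols(gr)$ref, mcols(gr)$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sample-to-population map TSV
#'
#' @param path TSV with columns `sample_id`, `population` (header required).
#' @return data.frame with those two columns.
#' @export
readPopulationMap <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "population") %in% names(df)))
  df
}

#' Read an ancestral-allele table TSV
#'
#' @param path TSV with columns `chrom`, `pos`, `ancestral` (header
#'   required); `ancestral` is a base or `NA`/`"."` for unknown.
#' @return data.frame with columns `chrom`, `pos`, `ancestral`.
#' @export
readAncestralTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  stopifnot(all(c("chrom", "pos", "ancestral") %in% names(df)))
  df$ancestral[df$ancestral %in% c(".", "")] <- NA_character_
  df
}

#' Read a trio table TSV
#'
#' @param path TSV with columns `child`, `sire`, `dam` (sample ids).
#' @return data.frame with those columns.
#' @export
readTrios <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("child", "sire", "dam") %in% names(df)))
  df
}

#' Read a pedigree table TSV
#'
#' @param path TSV with columns `animal`, `sire`, `dam`; unknown parents
#'   are `0`, `"."`, `""` or `NA`.
#' @return data.frame with columns `animal`, `sire`, `dam` (character;
#'   unknown parent = `NA`).
#' @export
readPedigree <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  for (col in c("sire", "dam"))
    df[[col]][df[[col]] %in% c("0", ".", "")] <- NA_character_
  df
}

#' Read gene models from BED or GFF3
#'
#' BED is interpreted 0-based half-open, GFF3 1-based inclusive (both are
#' normalized by rtracklayer into the 1-based closed `GRanges` convention
#' used internally). For GFF3, only `type == "gene"` features are kept.
#' Gene identifiers come from the BED `name` column or the GFF3 `ID`/
#' `gene_id` attribute; a `symbol` column is carried when present
#' (`Name` in GFF3), else it mirrors the id.
#'
#' @param path path to a `.bed`, `.gff3` or `.gff` file.
#' @param format override format detection (`"bed"` or `"gff3"`).
#' @return `GRanges` with metadata columns `gene_id` and `symbol`.
#' @export
readGenes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed" else "gff3"
  gr <- rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3")
  if (format == "gff3" && "type" %in% names(mcols(gr)))
    gr <- gr[as.character(mcols(gr)$type) == "gene"]
  mc <- mcols(gr)
  id <- if ("name" %in% names(mc)) as.character(mc$name)
        else if ("ID" %in% names(mc)) as.character(mc$ID)
        else if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
        else sprintf("gene%d", seq_along(gr))
  sym <- if ("Name" %in% names(mc)) as.character(mc$Name) else id
  if (anyDuplicated(id)) stop("gene identifiers must be unique")
  mcols(gr) <- S4Vectors::DataFrame(gene_id = id, symbol = sym)
  gr
}
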