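#' Write genotypes (with optional DP/GQ/AB) to a VCF file
#'
#' Minimal VCFv4.2 writer for the synthetic cohort: diploid unphased GT plus
#' optional per-genotype DP, GQ and AB FORMAT fields.
#'
#' @param path output path.
#' @param geno individuals x variants matrix in `{0,1,2}`/`NA`.
#' @param variants data frame with `variant_id`, `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param dp,gq,ab optional matrices matching `geno`.
#' @export
write_vcf <- function(path, geno, variants, dp = NULL, gq = NULL, ab = NULL) {
  n <- nrow(geno); m <- ncol(geno)
  stopifnot(nrow(variants) == m)
  samples <- rownames(geno) %||% sprintf("S%04d", seq_len(n))
  fmt <- c("GT", if (!is.null(dp)) "DP", if (!is.null(gq)) "GQ",
           if (!is.null(ab)) "AB")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (!is.null(dp)) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           if (!is.null(gq)) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
           if (!is.null(ab)) '##FORMAT=<ID=AB,Number=1,Type=Float,Description="Heterozygous allele balance">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], n, m)
  gt_str[is.na(geno)] <- "./."
  lines <- vapply(seq_len(m), function(j) {
    cells <- gt_str[, j]
    if (!is.null(dp)) cells <- paste(cells, dp[, j], sep = ":")
    if (!is.null(gq)) cells <- paste(cells, gq[, j], sep = ":")
    if (!is.null(ab)) cells <- paste(cells, sprintf("%.3f", ab[, j]), sep = ":")
    paste(c(variants$chrom[j], variants$pos[j], variants$variant_id[j],
            variants$ref[j], variants$alt[j], ".", "PASS", ".",
            paste(fmt, collapse = ":"), cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (tab-separated: set name, description, genes...).
#' @return named list of gene vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t")[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l) strsplit(l, "\t")[[1]][1],
                        character(1))
  sets
}

#' Write summary statistics to a GWAS-SSF-style TSV
#'
#' @param records summary-stat data frame ([run_scan()] output joined to a
#'   variant table with `chrom`, `pos`, `ref`, `alt`).
#' @param path output path.
#' @export
write_sumstats <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a summary statistics TSV
#' @param path input path.
#' @export
read_sumstats <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write regions as a BED file
#'
#' Regions are 1-based inclusive in memory and written as 0-based half-open
#' BED intervals.
#'
#' @param regions region data frame ([clump_regions()]).
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = paste0("chr", regions$chrom),
                    start = as.integer(regions$start - 1),
                    end = as.integer(regions$end),
                    name = regions$region_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a region data frame (1-based inclusive)
#' @param path BED path.
#' @export
read_regions_bed <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(region_id = if (ncol(d) >= 4) d[[4]] else sprintf("R%03d", seq_len(nrow(d))),
             chrom = as.numeric(sub("^chr", "", d[[1]])),
             start = d[[2]] + 1, end = d[[3]], stringsAsFactors = FALSE)
}
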