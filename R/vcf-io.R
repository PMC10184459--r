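#' Write a variant table as VCF v4.2
#'
#' Emits one record per locus with `GT:DP:GQ` sample fields, the gene id as
#' the chromosome, and the 1-based gene position. Absent calls are written
#' as `./.:.:.`.
#'
#' @param table A [variant_table()].
#' @param path Output `.vcf` path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(table, path) {
  samples <- sort(unique(table$sample))
  loci <- locus_summary(table)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=phyloskim",
    sprintf("##contig=<ID=%s>", sort(unique(loci$gene))),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  key <- paste(table$gene, table$pos)
  locus_key <- paste(loci$gene, loci$pos)
  cell <- ifelse(
    is.na(table$gt), "./.:.:.",
    sprintf("%s:%d:%d", table$gt, table$dp, as.integer(round(table$gq)))
  )
  cells <- matrix("", nrow = nrow(loci), ncol = length(samples))
  cells[cbind(match(key, locus_key), match(table$sample, samples))] <- cell
  body <- paste(
    loci$gene, loci$pos, ".", loci$ref, loci$alt, ".", "PASS", ".", "GT:DP:GQ",
    apply(cells, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF file into a variant table
#'
#' Parses a VCF with `GT`, `DP` and `GQ` FORMAT fields (via the vcfR
#' package) into the package's long genotype tibble.
#'
#' @param path Path to a `.vcf` or `.vcf.gz` file.
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  samples <- colnames(gt)
  n_loci <- nrow(fix)
  gt_chr <- as.vector(gt)
  gt_chr[gt_chr %in% c("./.", ".|.", ".")] <- NA_character_
  out <- tibble(
    sample = rep(samples, each = n_loci),
    gene = rep(fix$CHROM, times = length(samples)),
    pos = rep(as.integer(fix$POS), times = length(samples)),
    ref = rep(fix$REF, times = length(samples)),
    alt = rep(fix$ALT, times = length(samples)),
    gt = gt_chr,
    dp = as.integer(as.vector(dp)),
    gq = as.numeric(as.vector(gq))
  )
  out$dp[is.na(out$gt)] <- NA_integer_
  out$gq[is.na(out$gt)] <- NA_real_
  variant_table(out)
}
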