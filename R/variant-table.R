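#' Construct a genotype variant table
#'
#' The central container of the SNP workflow: one row per (sample, locus)
#' call, where a locus is a 1-based position on a gene CDS. Genotypes are
#' diploid VCF-style allele-index strings (`"0/0"`, `"0/1"`, `"1/2"`, ...),
#' with `NA` meaning the call is absent. `ref` holds the reference base and
#' `alt` the comma-separated alternate base(s), so a locus may declare more
#' than two alleles even though downstream filters will restrict it to
#' biallelic SNPs. Depth (`dp`) and quality (`gq`) are `NA` exactly when the
#' genotype is absent.
#'
#' The table is kept as a full grid: every sample appears at every locus,
#' absent calls included, so per-locus missing fractions are always computed
#' against the complete sample list.
#'
#' @param x A data frame with columns `sample`, `gene`, `pos`, `ref`, `alt`,
#'   `gt`, `dp`, `gq`.
#' @return A `skim_variants` tibble.
#' @export
variant_table <- function(x) {
  required <- c("sample", "gene", "pos", "ref", "alt", "gt", "dp", "gq")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop_invalid(paste0(
      "variant table is missing column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  x <- as_tibble(x)
  x$pos <- as.integer(x$pos)
  x$dp <- as.integer(x$dp)
  x$gq <- as.numeric(x$gq)
  present <- !is.na(x$gt)
  if (any(present & (is.na(x$dp) | x$dp < 1))) {
    stop_invalid("present calls must carry depth >= 1")
  }
  # genotype strings must parse
  invisible(gt_allele_matrix(x$gt))
  # full grid: every sample at every locus
  n_samp <- dplyr::n_distinct(x$sample)
  key <- paste(x$gene, x$pos)
  if (anyDuplicated(paste(x$sample, key))) {
    stop_invalid("duplicate (sample, gene, pos) rows")
  }
  locus_n <- table(key)
  if (any(locus_n != n_samp)) {
    stop_invalid("every locus must have one row per sample (use NA gt for absent calls)")
  }
  class(x) <- c("skim_variants", class(x)[!class(x) %in% "skim_variants"])
  x
}

# Re-tag a tibble that is known to satisfy the variant-table contract,
# preserving attributes such as the filter flag.
retag_variants <- function(x, template = NULL) {
  class(x) <- unique(c("skim_variants", class(x)))
  if (!is.null(template)) {
    attr(x, "filtered") <- attr(template, "filtered")
    attr(x, "audit") <- attr(template, "audit")
  }
  x
}

#' @export
print.skim_variants <- function(x, ...) {
  ls <- locus_summary(x)
  cat(sprintf(
    "<skim_variants> %d samples x %d loci (%d genes); mean missing %.3f\n",
    dplyr::n_distinct(x$sample), nrow(ls),
    dplyr::n_distinct(x$gene), mean(is.na(x$gt))
  ))
  NextMethod()
}

#' Per-locus summary of a variant table
#'
#' @param table A `skim_variants` tibble.
#' @return A tibble with one row per locus: occupancy (fraction of samples
#'   with a present call), missing fraction, the observed allele indices and
#'   the number of distinct observed alleles.
#' @export
locus_summary <- function(table) {
  al <- gt_allele_matrix(table$gt)
  df <- tibble(
    gene = table$gene, pos = table$pos, ref = table$ref, alt = table$alt,
    present = !is.na(table$gt), a1 = al[, 1], a2 = al[, 2]
  )
  df |>
    group_by(.data$gene, .data$pos, .data$ref, .data$alt) |>
    summarise(
      n_samples = n(),
      n_present = sum(.data$present),
      occupancy = mean(.data$present),
      # n_absent / n gives the same binary representation as the m/100
      # thresholds on exact boundaries, keeping strict comparisons exact
      missing_fraction = sum(!.data$present) / n(),
      n_alleles = dplyr::n_distinct(c(.data$a1[.data$present], .data$a2[.data$present])),
      .groups = "drop"
    ) |>
    arrange(.data$gene, .data$pos)
}

# Bases (ref first, then alts in declared order) for one locus.
locus_alleles <- function(ref, alt) c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
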