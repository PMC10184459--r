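#' Filter configuration for the SNP filter cascade
#'
#' Holds the thresholds of the coverage/quality window, the minor-allele
#' sharing filter and the missing-data gradient scan. Defaults are the
#' workflow's standard values: calls are kept when their depth lies between
#' 0.5 and 2 times the sample's median coverage (inclusive) and their
#' quality is at least 20; SNPs carried by fewer than three samples are
#' discarded; per-sample medians are computed over loci present in strictly
#' more than half the samples; the gradient scan enumerates nine missing-data
#' thresholds from 10 to 90 percent.
#'
#' @param coverage_low_mult,coverage_high_mult Multiples of the per-sample
#'   median depth bounding the kept coverage window (inclusive).
#' @param min_quality Minimum phred-like call quality.
#' @param min_shared Minimum number of samples carrying the minor allele.
#' @param median_occupancy_min Strict lower bound on locus occupancy for the
#'   median-coverage computation.
#' @param gradient_thresholds Missing-data thresholds, in percent.
#' @return A `filter_config` list.
#' @export
filter_config <- function(coverage_low_mult = 0.5, coverage_high_mult = 2,
                          min_quality = 20, min_shared = 3,
                          median_occupancy_min = 0.5,
                          gradient_thresholds = seq(10, 90, by = 10)) {
  if (coverage_low_mult <= 0 || coverage_low_mult >= coverage_high_mult) {
    stop_invalid("need 0 < coverage_low_mult < coverage_high_mult")
  }
  if (is.unsorted(gradient_thresholds, strictly = TRUE)) {
    stop_invalid("gradient_thresholds must be strictly increasing")
  }
  structure(
    list(
      coverage_low_mult = coverage_low_mult,
      coverage_high_mult = coverage_high_mult,
      min_quality = min_quality,
      min_shared = min_shared,
      median_occupancy_min = median_occupancy_min,
      gradient_thresholds = gradient_thresholds
    ),
    class = "filter_config"
  )
}

#' Per-sample median coverage over well-occupied loci
#'
#' For each sample, the median depth of its present calls, restricted to
#' loci whose occupancy (fraction of samples with a present call) is
#' strictly greater than `median_occupancy_min`. Medians over an even number
#' of depths are the mean of the two middle values.
#'
#' @param table A [variant_table()].
#' @param samples Samples to report; defaults to all.
#' @param median_occupancy_min Strict occupancy bound (default 0.5).
#' @return A tibble with columns `sample`, `median_dp`, `n_calls`.
#' @export
median_site_coverage <- function(table, samples = NULL,
                                 median_occupancy_min = 0.5) {
  all_samples <- unique(table$sample)
  if (is.null(samples)) samples <- all_samples
  unknown <- setdiff(samples, all_samples)
  if (length(unknown) > 0) {
    stop_invalid(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")))
  }
  occ <- table |>
    group_by(.data$gene, .data$pos) |>
    summarise(occupancy = mean(!is.na(.data$gt)), .groups = "drop") |>
    filter(.data$occupancy > median_occupancy_min)
  qual <- table |>
    inner_join(occ, by = c("gene", "pos")) |>
    filter(.data$sample %in% samples, !is.na(.data$gt))
  out <- qual |>
    group_by(.data$sample) |>
    summarise(median_dp = median(.data$dp), n_calls = n(), .groups = "drop")
  absent <- setdiff(samples, out$sample)
  if (length(absent) > 0) {
    abort(
      paste0(
        "no qualifying calls (occupancy > ",
        median_occupancy_min, ") for sample(s): ",
        paste(absent, collapse = ", ")
      ),
      class = c("phyloskim_no_data", "phyloskim_error")
    )
  }
  out |> arrange(match(.data$sample, samples))
}

# Attach/extend the audit trail recorded on a variant table.
append_audit <- function(table, stage, loci_in, loci_out, calls_removed = NA_integer_) {
  audit <- attr(table, "audit")
  row <- tibble(
    stage = stage, loci_in = loci_in, loci_out = loci_out,
    loci_removed = loci_in - loci_out, calls_removed = as.integer(calls_removed)
  )
  attr(table, "audit") <- if (is.null(audit)) row else bind_rows(audit, row)
  table
}

n_loci_of <- function(table) nrow(distinct(table, .data$gene, .data$pos))

#' Coverage-window and quality filter
#'
#' Sets a call to absent unless its depth lies within
#' `[coverage_low_mult, coverage_high_mult]` times its own sample's median
#' coverage (both boundaries inclusive) and its quality is at least
#' `min_quality`. Medians are those of [median_site_coverage()] computed on
#' the input table. Loci left without any present call are dropped.
#'
#' @param table A [variant_table()].
#' @param config A [filter_config()].
#' @return The filtered `skim_variants` tibble, with the audit trail in
#'   `attr(, "audit")`.
#' @export
coverage_quality_filter <- function(table, config = filter_config()) {
  loci_in <- n_loci_of(table)
  med <- median_site_coverage(
    table,
    median_occupancy_min = config$median_occupancy_min
  )
  out <- table |>
    left_join(med |> select("sample", "median_dp"), by = "sample") |>
    mutate(
      keep = !is.na(.data$gt) &
        .data$dp >= config$coverage_low_mult * .data$median_dp &
        .data$dp <= config$coverage_high_mult * .data$median_dp &
        .data$gq >= config$min_quality
    )
  calls_removed <- sum(!is.na(out$gt) & !out$keep)
  out <- out |>
    mutate(
      gt = ifelse(.data$keep, .data$gt, NA_character_),
      dp = ifelse(.data$keep, .data$dp, NA_integer_),
      gq = ifelse(.data$keep, .data$gq, NA_real_)
    ) |>
    select(-"median_dp", -"keep") |>
    group_by(.data$gene, .data$pos) |>
    filter(any(!is.na(.data$gt))) |>
    ungroup()
  out <- retag_variants(out, table)
  append_audit(out, "coverage_quality", loci_in, n_loci_of(out), calls_removed)
}

# Observed allele indices (across present calls) per locus.
observed_allele_counts <- function(table) {
  al <- gt_allele_matrix(table$gt)
  tibble(
    gene = rep(table$gene, 2), pos = rep(table$pos, 2),
    allele = c(al[, 1], al[, 2])
  ) |>
    filter(!is.na(.data$allele)) |>
    distinct(.data$gene, .data$pos, .data$allele) |>
    count(.data$gene, .data$pos, name = "n_alleles")
}

#' Biallelic SNP filter
#'
#' Retains only loci with exactly two distinct alleles observed across
#' present calls: loci with more than two observed alleles are removed, and
#' so are loci monomorphic after earlier filtering (a single observed
#' allele is not a SNP).
#'
#' @inheritParams coverage_quality_filter
#' @return The filtered `skim_variants` tibble.
#' @export
biallelic_filter <- function(table) {
  loci_in <- n_loci_of(table)
  keep <- observed_allele_counts(table) |> filter(.data$n_alleles == 2)
  out <- table |> inner_join(keep |> select("gene", "pos"), by = c("gene", "pos"))
  out <- retag_variants(out, table)
  append_audit(out, "biallelic", loci_in, n_loci_of(out))
}

#' Minor-allele sharing filter
#'
#' Retains a locus only when the minor allele has been observed at least
#' `min_shared` times across the present diploid genotypes, counting allele
#' copies as a minor-allele-count filter does (a heterozygote contributes
#' one copy, a homozygote two); more rarely shared SNPs are discarded as
#' likely artefacts of low coverage and sequencing error. The minor allele
#' is the observed allele with the fewest copies; loci without two observed
#' alleles are removed.
#'
#' @inheritParams coverage_quality_filter
#' @param min_shared Minimum minor-allele copy count (default 3).
#' @return The filtered `skim_variants` tibble.
#' @export
shared_count_filter <- function(table, min_shared = 3) {
  if (inherits(min_shared, "filter_config")) min_shared <- min_shared$min_shared
  loci_in <- n_loci_of(table)
  al <- gt_allele_matrix(table$gt)
  copies <- tibble(
    gene = rep(table$gene, 2), pos = rep(table$pos, 2),
    allele = c(al[, 1], al[, 2])
  ) |>
    filter(!is.na(.data$allele)) |>
    count(.data$gene, .data$pos, .data$allele, name = "n_copies")
  keep <- copies |>
    group_by(.data$gene, .data$pos) |>
    summarise(
      n_obs_alleles = n(),
      minor_copies = min(.data$n_copies),
      .groups = "drop"
    ) |>
    filter(.data$n_obs_alleles >= 2, .data$minor_copies >= min_shared)
  out <- table |> inner_join(keep |> select("gene", "pos"), by = c("gene", "pos"))
  out <- retag_variants(out, table)
  append_audit(out, "shared_count", loci_in, n_loci_of(out))
}

#' Run the full SNP filter cascade
#'
#' Applies, in order: the coverage-window/quality filter, the biallelic
#' filter and the minor-allele sharing filter. The result carries an audit
#' trail (`attr(, "audit")`: loci in/out and calls removed per stage) and is
#' flagged as filtered so downstream stages can enforce their precondition.
#'
#' @inheritParams coverage_quality_filter
#' @return The filtered `skim_variants` tibble with `attr(, "filtered")`
#'   set.
#' @export
filter_cascade <- function(table, config = filter_config()) {
  out <- table |>
    coverage_quality_filter(config) |>
    biallelic_filter() |>
    shared_count_filter(config$min_shared)
  attr(out, "filtered") <- TRUE
  out
}

#' Missing-data gradient scan
#'
#' For each threshold `m` (percent), counts the loci whose fraction of
#' absent calls is strictly below `m / 100`, so that a "maximum of m percent
#' missing data" admits loci below the threshold. Counts are non-decreasing
#' in `m` because the admitted sets are nested.
#'
#' @inheritParams coverage_quality_filter
#' @param thresholds Percent thresholds (default the nine values 10-90).
#' @return A tibble with columns `threshold` and `n_loci`.
#' @export
missing_gradient_scan <- function(table, thresholds = seq(10, 90, by = 10)) {
  if (inherits(thresholds, "filter_config")) thresholds <- thresholds$gradient_thresholds
  frac <- locus_summary(table)$missing_fraction
  tibble(
    threshold = as.integer(thresholds),
    n_loci = vapply(thresholds, function(m) sum(frac < m / 100), numeric(1))
  )
}

#' Write the filter audit trail
#'
#' @param table A filtered `skim_variants` tibble.
#' @param path Output path for a tab-separated audit log.
#' @return The audit tibble, invisibly.
#' @export
write_filter_audit <- function(table, path) {
  audit <- attr(table, "audit")
  if (is.null(audit)) stop_invalid("table carries no audit trail")
  readr::write_tsv(audit, path)
  invisible(audit)
}
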