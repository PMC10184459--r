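# The SNP filter cascade: median coverage, coverage/quality window,
# biallelic restriction, minor-allele sharing, missing-data gradient.

test_that("median coverage follows the mean-of-middles convention", {
  s <- "s01"
  odd <- toy_table(s, list(
    list(gene = "g1", pos = 1L, gt = c(s01 = "0/1"), dp = c(s01 = 1L)),
    list(gene = "g1", pos = 2L, gt = c(s01 = "0/1"), dp = c(s01 = 4L)),
    list(gene = "g1", pos = 3L, gt = c(s01 = "0/1"), dp = c(s01 = 9L))
  ))
  expect_equal(median_site_coverage(odd)$median_dp, 4)

  even <- toy_table(s, list(
    list(gene = "g1", pos = 1L, gt = c(s01 = "0/1"), dp = c(s01 = 2L)),
    list(gene = "g1", pos = 2L, gt = c(s01 = "0/1"), dp = c(s01 = 4L)),
    list(gene = "g1", pos = 3L, gt = c(s01 = "0/1"), dp = c(s01 = 6L)),
    list(gene = "g1", pos = 4L, gt = c(s01 = "0/1"), dp = c(s01 = 10L))
  ))
  expect_equal(median_site_coverage(even)$median_dp, 5)
})

test_that("loci at exactly 50% occupancy are excluded from the median set", {
  samples <- sprintf("s%02d", 1:10)
  tab <- toy_table(samples, list(
    # present in 5 of 10 samples: occupancy 0.5, NOT > 0.5
    list(gene = "g1", pos = 1L, dp = c(s01 = 99L),
         absent = sprintf("s%02d", 6:10)),
    list(gene = "g1", pos = 2L, dp = c(s01 = 4L)),
    list(gene = "g1", pos = 3L, dp = c(s01 = 6L))
  ))
  med <- median_site_coverage(tab, samples = "s01")
  expect_equal(med$median_dp, 5)  # {4, 6}; the dp-99 locus contributes nothing
  expect_equal(med$n_calls, 2)
})

test_that("samples without qualifying calls raise a no-data error", {
  samples <- sprintf("s%02d", 1:4)
  tab <- toy_table(samples, list(
    list(gene = "g1", pos = 1L, absent = "s02"),
    list(gene = "g1", pos = 2L, absent = "s02")
  ))
  expect_error(median_site_coverage(tab), "s02",
               class = "phyloskim_no_data")
  expect_error(median_site_coverage(tab, samples = "zz"),
               class = "phyloskim_invalid_input")
})

test_that("the coverage window is inclusive and quality 19 fails", {
  toy <- cascade_toy()
  out <- coverage_quality_filter(toy)
  g1_1 <- out |> dplyr::filter(gene == "g1", pos == 1)
  gt_of <- function(tab, s) tab$gt[tab$sample == s]
  # window [5, 20] around median 10: boundaries kept, outside removed
  expect_false(is.na(gt_of(g1_1, "s01")))  # dp 5
  expect_false(is.na(gt_of(g1_1, "s02")))  # dp 20
  expect_true(is.na(gt_of(g1_1, "s03")))   # dp 4
  expect_true(is.na(gt_of(g1_1, "s04")))   # dp 21
  expect_true(is.na(gt_of(g1_1, "s05")))   # dp 1
  g1_2 <- out |> dplyr::filter(gene == "g1", pos == 2)
  expect_true(is.na(gt_of(g1_2, "s01")))   # quality 19 < 20
  expect_false(is.na(gt_of(g1_2, "s02")))  # quality 20 kept
})

test_that("the cascade stages drop the hand-counted loci", {
  toy <- cascade_toy()
  filtered <- filter_cascade(toy)
  audit <- attr(filtered, "audit")
  expect_equal(audit$stage, c("coverage_quality", "biallelic", "shared_count"))
  expect_equal(audit$loci_in, c(20L, 20L, 17L))
  expect_equal(audit$loci_out, c(20L, 17L, 15L))
  expect_equal(audit$calls_removed[1], 4L)
  expect_true(isTRUE(attr(filtered, "filtered")))

  kept <- locus_summary(filtered)
  key <- paste(kept$gene, kept$pos)
  expect_false(any(c("g1 3", "g1 4", "g1 8") %in% key))  # biallelic stage
  expect_false(any(c("g1 6", "g1 9") %in% key))          # sharing stage
  expect_true(all(c("g1 1", "g1 2", "g1 5", "g1 7", "g2 10") %in% key))

  # filters only remove: counts monotone non-increasing through the cascade
  expect_true(all(diff(c(audit$loci_in[1], audit$loci_out)) <= 0))
})

test_that("re-running a stage is idempotent", {
  filtered <- filter_cascade(cascade_toy())
  again_bi <- biallelic_filter(filtered)
  again_sh <- shared_count_filter(filtered)
  expect_equal(n_distinct_loci <- nrow(locus_summary(again_bi)),
               nrow(locus_summary(filtered)))
  expect_equal(nrow(locus_summary(again_sh)), nrow(locus_summary(filtered)))
  cq <- coverage_quality_filter(filtered)
  expect_equal(sum(is.na(cq$gt)), sum(is.na(filtered$gt)))
})

test_that("the cascade is the identity on clean well-shared data", {
  samples <- sprintf("s%02d", 1:8)
  loci <- lapply(1:12, function(i) {
    list(gene = "g1", pos = as.integer(i),
         gt = c(s01 = "0/1", s02 = "0/1", s03 = "0/1"))
  })
  tab <- toy_table(samples, loci)  # dp uniformly 10, gq 99, 3 carriers
  out <- filter_cascade(tab)
  expect_equal(nrow(locus_summary(out)), 12)
  expect_equal(sum(is.na(out$gt)), 0)
})

test_that("the gradient scan enumerates nine nested thresholds", {
  # loci engineered to missing fractions {0, .2, .45, .55, .7, .95} over 20 samples
  samples <- sprintf("s%02d", 1:20)
  absences <- c(0, 4, 9, 11, 14, 19)
  loci <- lapply(seq_along(absences), function(i) {
    list(gene = "g1", pos = as.integer(i),
         gt = c(s01 = "0/1", s02 = "0/1", s03 = "0/1", s04 = "0/1", s05 = "0/1"),
         absent = if (absences[i] > 0) sprintf("s%02d", 21 - seq_len(absences[i])))
  })
  tab <- toy_table(samples, loci)
  scan <- missing_gradient_scan(tab)
  expect_equal(nrow(scan), 9)
  expect_equal(scan$threshold, seq(10L, 90L, 10L))
  expect_equal(scan$n_loci[scan$threshold == 50], 3)
  expect_equal(scan$n_loci[scan$threshold == 80], 5)
  expect_true(all(diff(scan$n_loci) >= 0))

  # and on the hand-counted cascade toy
  scan2 <- missing_gradient_scan(filter_cascade(cascade_toy()))
  expect_equal(scan2$n_loci, c(12, 13, 13, 14, 14, 15, 15, 15, 15))
})

test_that("filter config validates its thresholds", {
  expect_error(filter_config(coverage_low_mult = 3, coverage_high_mult = 2),
               class = "phyloskim_invalid_input")
  expect_error(filter_config(gradient_thresholds = c(10, 10, 30)),
               class = "phyloskim_invalid_input")
})
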