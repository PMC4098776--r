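# Expected HWE p-values below were computed in advance with the
# independent Levene-Haldane enumeration oracle (hwe_oracle in
# helper-fixtures.R) and frozen.

test_that("HWE exact p matches the enumeration oracle", {
  expect_equal(hwe_exact_pvalue(100, 0, 0), 1.0)
  # 10 minor alleles in 10 diploids, het counts {0,2,...,10}
  expect_equal(hwe_exact_pvalue(5, 0, 5), 0.001363961116283096,
               tolerance = 1e-12)
  expect_equal(hwe_exact_pvalue(57, 14, 50), 5.562047311095723e-19,
               tolerance = 1e-6)
  expect_equal(hwe_exact_pvalue(57, 14, 50), hwe_oracle(57, 14, 50))
  expect_error(hwe_exact_pvalue(0, 0, 0), "no genotypes")
})

test_that("HWE exact p agrees with the oracle on all small configurations", {
  # exhaustive up to 16 diploids here; the full <=50 sweep runs in the
  # acceptance suite
  for (n in 1:16) {
    for (a in 0:n) for (h in 0:(n - a)) {
      b <- n - a - h
      expect_equal(hwe_exact_pvalue(a, h, b), hwe_oracle(a, h, b),
                   tolerance = 1e-12,
                   label = sprintf("hwe(%d,%d,%d)", a, h, b))
    }
  }
})

test_that("HWE exact p is invariant under allele relabeling", {
  set.seed(7)
  for (i in 1:50) {
    a <- sample(0:40, 1); h <- sample(0:40, 1); b <- sample(0:40, 1)
    if (a + h + b == 0) next
    expect_equal(hwe_exact_pvalue(a, h, b), hwe_exact_pvalue(b, h, a))
  }
})

test_that("HWE filter removes variants below the Bonferroni threshold", {
  sim <- small_sim()
  ds <- apply_genotype_filters(sim$dataset, 8, 20)$dataset
  res <- hwe_filter(ds, alpha = 0.05)
  expect_equal(res$threshold, 0.05 / res$n_tested)
  expect_true(all(res$removed$hwe_p <= res$threshold))
  expect_equal(nrow(res$dataset$variants) + nrow(res$removed),
               nrow(ds$variants))
  # an absurdly small alpha removes nothing
  res0 <- hwe_filter(ds, alpha = 1e-300)
  expect_equal(nrow(res0$removed), 0)
  # removals are enriched for the generated heterozygote-excess sites
  lab <- sim$truth$labels
  removed_keys <- variant_keys(res$removed)
  viol_rate <- mean(variant_keys(lab)[lab$hwe_violating] %in% removed_keys)
  conf_rate <- mean(variant_keys(lab)[!lab$hwe_violating] %in% removed_keys)
  expect_gt(viol_rate, conf_rate)
})

test_that("average GQ and call rate follow their definitions", {
  variants <- data.frame(chrom = "1", pos = 1:2, ref = "A", alt = "G",
                         vqsr_pass = TRUE)
  ds <- cohort_dataset(paste0("s", 1:4), variants,
                       gt = rbind(c(0L, 1L, 2L, NA), c(1L, NA, NA, NA)),
                       gq = rbind(c(20L, 30L, 40L, 99L),
                                  c(99L, NA, NA, NA)))
  expect_equal(average_gq(ds), c(30, 99))
  expect_equal(call_rate(ds), c(0.75, 0.25))
  all_missing <- cohort_dataset("s1", variants[1, ],
                                gt = matrix(NA_integer_),
                                gq = matrix(50L))
  expect_error(average_gq(all_missing), "no non-missing")
  expect_equal(call_rate(all_missing), 0)
  all_called <- ds[1, ]
  all_called$gt[1, 4] <- 0L
  expect_equal(call_rate(all_called), 1)
})

test_that("the VQSR verdict retains passing variants only", {
  variants <- data.frame(chrom = "1", pos = 1:10, ref = "A", alt = "G",
                         vqsr_pass = rep(c(TRUE, FALSE), c(7, 3)))
  ds <- cohort_dataset("s1", variants, gt = matrix(0L, 10, 1))
  res <- apply_vqsr(ds)
  expect_equal(nrow(res$dataset$variants), 7)
  expect_equal(nrow(res$removed), 3)
  all_pass <- apply_vqsr(res$dataset)
  expect_equal(all_pass$dataset$variants, res$dataset$variants)
  none <- ds
  none$variants$vqsr_pass <- FALSE
  expect_equal(nrow(apply_vqsr(none)$dataset$variants), 0)
})

test_that("the cascade removes at the stated stage and keeps its books", {
  sim <- small_sim()
  ds <- apply_genotype_filters(sim$dataset, 8, 20)$dataset
  th <- filter_thresholds()
  res <- apply_variant_filters(ds, th)
  expect_equal(res$report$stage, c("hwe", "avg_gq", "call_rate", "vqsr"))
  expect_equal(sum(res$report$n_removed) + nrow(res$dataset$variants),
               nrow(ds$variants))
  expect_equal(res$report$n_remaining[4], nrow(res$dataset$variants))
  # a variant at call rate just under threshold is removed at that stage
  cr <- call_rate(ds)
  ag <- average_gq(ds)
  hwe_keys <- variant_keys(attr(res$report, "removed")$hwe)
  below <- !is.na(ag) & ag >= th$min_avg_gq & cr < th$min_call_rate &
    !(variant_keys(ds) %in% hwe_keys)
  cr_removed <- variant_keys(attr(res$report, "removed")$call_rate)
  expect_setequal(variant_keys(ds)[below], cr_removed)
})

test_that("disabled thresholds make the cascade the identity", {
  ds <- make_tiny_cohort()
  th <- filter_thresholds(hwe_alpha = 1e-300, min_avg_gq = 0,
                          min_call_rate = 0, vqsr_position = "off")
  res <- apply_variant_filters(ds, th)
  expect_equal(res$dataset$variants, ds$variants)
  expect_equal(res$dataset$gt, ds$gt)
})

test_that("cascade equals a composition of its primitive stages", {
  sim <- small_sim()
  ds <- apply_genotype_filters(sim$dataset, 8, 20)$dataset
  th <- filter_thresholds()
  for (pos in c("after_manual", "before_manual")) {
    th$vqsr_position <- pos
    got <- apply_variant_filters(ds, th)$dataset
    d <- ds
    if (pos == "before_manual") d <- apply_vqsr(d)$dataset
    d <- hwe_filter(d, th$hwe_alpha)$dataset
    ag <- average_gq(d)
    d <- d[!is.na(ag) & ag >= th$min_avg_gq, ]
    d <- d[call_rate(d) >= th$min_call_rate, ]
    if (pos == "after_manual") d <- apply_vqsr(d)$dataset
    expect_equal(got$variants, d$variants)
    expect_equal(got$gt, d$gt)
  }
})

test_that("variant filters are idempotent and monotone in stringency", {
  sim <- small_sim()
  ds <- apply_genotype_filters(sim$dataset, 8, 20)$dataset
  th <- filter_thresholds()
  once <- apply_variant_filters(ds, th)$dataset
  twice <- apply_variant_filters(once, th)$dataset
  # HWE is re-tested with a smaller Bonferroni N on the survivors, so
  # idempotence is checked per deterministic-threshold stage
  ag_once <- ds[!is.na(average_gq(ds)) & average_gq(ds) >= 35, ]
  ag_twice <- ag_once[!is.na(average_gq(ag_once)) &
                        average_gq(ag_once) >= 35, ]
  expect_equal(ag_twice$variants, ag_once$variants)
  expect_lte(nrow(twice$variants), nrow(once$variants))
  n_strict <- nrow(apply_variant_filters(
    ds, filter_thresholds(min_call_rate = 0.95))$dataset$variants)
  expect_lte(n_strict, nrow(once$variants))
})
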