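test_that("genotype pairs classify by alternate-allele dosage", {
  expect_equal(classify_genotype_pair("HET", "HOM_ALT"), "FN")
  expect_equal(classify_genotype_pair("HOM_ALT", "HET"), "FP")
  expect_equal(classify_genotype_pair("MISSING", "HET"), "EXCLUDED")
  expect_equal(classify_genotype_pair("HOM_REF", "HOM_REF"), "TN")
  expect_equal(classify_genotype_pair("HET", "HET"), "TP")
  expect_equal(classify_genotype_pair("HOM_ALT", "HOM_ALT"), "TP")
  expect_equal(classify_genotype_pair(NA, 1), "EXCLUDED")
  expect_error(classify_genotype_pair("HET", "MISSING"), "missing")
})

test_that("classification is exhaustive and symmetric over called pairs", {
  pairs <- expand.grid(wes = 0:2, array = 0:2)
  cls <- classify_genotype_pair(pairs$wes, pairs$array)
  expect_true(all(cls %in% c("TP", "TN", "FP", "FN")))
  # swapping the roles maps FP <-> FN and fixes TP/TN
  swapped <- classify_genotype_pair(pairs$array, pairs$wes)
  map <- c(TP = "TP", TN = "TN", FP = "FN", FN = "FP")
  expect_equal(unname(map[cls]), swapped)
})

test_that("concordance report aggregates the four classes", {
  variants <- data.frame(chrom = "1", pos = 1:4, ref = "A", alt = "G",
                         vqsr_pass = TRUE)
  ds <- cohort_dataset("S1", variants,
                       gt = matrix(c(0L, 1L, 0L, 1L), 4, 1))
  arr <- array_genotypes(data.frame(
    sample = "S1", chrom = "1", pos = 1:4, ref = "A", alt = "G",
    genotype = c("HOM_REF", "HET", "HET", "HOM_REF"),
    gencall_score = 0.9))
  tab <- concordance_report(ds, arr)
  expect_equal(tab$tn, 1); expect_equal(tab$tp, 1)
  expect_equal(tab$fn, 1); expect_equal(tab$fp, 1)
  expect_equal(tab$n_compared, 4)
  # array non-reference comparisons: the two HETs; reference: the rest
  expect_equal(tab$nonref_concordant + tab$nonref_discordant, 2)
  expect_equal(tab$ref_concordant + tab$ref_discordant, 2)
})

test_that("sites absent from the callset or with allele mismatch are excluded", {
  variants <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "G",
                         vqsr_pass = TRUE)
  ds <- cohort_dataset("S1", variants, gt = matrix(1L))
  off <- array_genotypes(data.frame(
    sample = "S1", chrom = "2", pos = 5L, ref = "A", alt = "G",
    genotype = "HET", gencall_score = 0.9))
  expect_equal(concordance_report(ds, off)$n_compared, 0)
  mism <- array_genotypes(data.frame(
    sample = "S1", chrom = "1", pos = 1L, ref = "A", alt = "T",
    genotype = "HET", gencall_score = 0.9))
  expect_message(tab <- concordance_report(ds, mism), "allele mismatch")
  expect_equal(tab$n_compared, 0)
})

test_that("the report equals a brute-force per-pair reclassification", {
  sim <- simulate_cohort(sim_config(n_samples = 15, n_variants = 300,
                                    seed = 5L))
  arr <- simulate_array(sim$truth, sample_subset = sim$truth$samples[1:6],
                        array_error_rate = 0.01, seed = 9L)
  tab <- concordance_report(sim$dataset, arr)
  # independent pairwise oracle
  counts <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  nonref_disc <- 0; ref_disc <- 0
  vk <- variant_keys(sim$dataset)
  for (i in seq_len(nrow(arr))) {
    key <- paste(arr$chrom[i], arr$pos[i], arr$ref[i], arr$alt[i],
                 sep = ":")
    vi <- match(key, vk)
    si <- match(arr$sample[i], sim$dataset$samples)
    if (is.na(vi) || is.na(si)) next
    w <- sim$dataset$gt[vi, si]
    if (is.na(w)) next
    a <- arr$genotype[i]
    cls <- if (w == a && a == 0) "TN" else if (w == a) "TP"
           else if (w < a) "FN" else "FP"
    counts[cls] <- counts[cls] + 1
    if (a > 0 && cls != "TP") nonref_disc <- nonref_disc + 1
    if (a == 0 && cls != "TN") ref_disc <- ref_disc + 1
  }
  expect_equal(tab$tp, unname(counts["TP"]))
  expect_equal(tab$tn, unname(counts["TN"]))
  expect_equal(tab$fp, unname(counts["FP"]))
  expect_equal(tab$fn, unname(counts["FN"]))
  expect_equal(tab$nonref_discordant, nonref_disc)
  expect_equal(tab$ref_discordant, ref_disc)
})

test_that("metrics and removal fractions follow their definitions", {
  tab <- concordance_counts(tp = 1, tn = 1, fp = 0, fn = 0)
  m <- metrics_from_counts(tab)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  zero <- concordance_counts(tp = 0, tn = 5, fp = 0, fn = 0)
  expect_true(is.na(metrics_from_counts(zero)$sensitivity))

  before <- concordance_counts(tp = 100, tn = 50, fp = 4, fn = 20)
  same <- removal_fractions(before, before)
  expect_equal(same$pct_concordant_removed, 0)
  expect_equal(same$pct_discordant_removed, 0)
  after <- concordance_counts(tp = 90, tn = 50, fp = 4, fn = 10)
  rf <- removal_fractions(before, after)
  expect_equal(rf$pct_concordant_removed, 0.1)
  expect_equal(rf$pct_discordant_removed, 0.5)
  bigger <- concordance_counts(tp = 101, tn = 50, fp = 4, fn = 20)
  expect_error(removal_fractions(before, bigger), "exceed")
})

test_that("with a perfect array, discordance reflects injected errors", {
  sim <- small_sim()
  arr <- simulate_array(sim$truth, sample_subset = sim$truth$samples,
                        array_error_rate = 0, low_gencall_frac = 0,
                        seed = 13L)
  tab <- concordance_report(sim$dataset, arr)
  # every discordant comparison is an injected error; every concordant
  # one is error-free (the array equals the truth)
  n_err_called <- sum(sim$truth$error & !is.na(sim$dataset$gt))
  expect_equal(tab$fp + tab$fn, n_err_called)
  expect_equal(tab$n_compared, sum(!is.na(sim$dataset$gt)))
})
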