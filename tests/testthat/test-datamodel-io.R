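test_that("read_vcf selects biallelic SNVs and decodes fields", {
  path <- write_fixture_vcf()
  expect_message(ds <- read_vcf(path), "non-SNV record\\(s\\) skipped")
  # 2 plain SNVs + triallelic split into 2; indel skipped
  expect_equal(length(ds$samples), 3)
  expect_equal(nrow(ds$variants), 4)
  expect_equal(sum(ds$variants$pos == 400), 2)
  tri <- ds$variants[ds$variants$pos == 400, ]
  expect_equal(tri$ref, c("T", "T"))
  expect_setequal(tri$alt, c("A", "C"))
  # genotype dosages per split alternate: S1 is 1/2
  g400 <- ds$gt[ds$variants$pos == 400, ]
  expect_equal(unname(g400[, "S1"]), c(1L, 1L))
  # non-PASS FILTER fails the VQSR verdict
  expect_false(ds$variants$vqsr_pass[ds$variants$pos == 200])
  expect_true(ds$variants$vqsr_pass[ds$variants$pos == 100])
  # DP/GQ decoded; missing genotype keeps NA fields
  expect_equal(unname(ds$dp[1, ]), c(12L, 8L, 40L))
  expect_true(is.na(ds$gt[2, 2]) && is.na(ds$dp[2, 2]))
})

test_that("multiallelic records are skipped when splitting is off", {
  path <- write_fixture_vcf()
  suppressMessages(
    expect_message(ds <- read_vcf(path, split_multiallelic = FALSE),
                   "multiallelic"))
  expect_equal(nrow(ds$variants), 2)
})

test_that("half-missing genotypes are coerced to missing", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", sep = "\t"),
    paste("1", "10", ".", "A", "C", ".", ".", ".", "GT",
          "0/.", "1/1", sep = "\t")
  ), path)
  expect_message(ds <- read_vcf(path), "half-missing")
  expect_true(is.na(ds$gt[1, 1]))
  expect_equal(ds$gt[1, 2], c(S2 = 2L))
  # "." FILTER maps to a passing verdict (pre-VQSR VCFs)
  expect_true(ds$variants$vqsr_pass)
})

test_that("non-diploid GT is an error", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t"),
    paste("1", "10", ".", "A", "C", ".", ".", ".", "GT", "1", sep = "\t")
  ), path)
  expect_error(read_vcf(path), "ploidy")
})

test_that("write_vcf / read_vcf round-trips the data model", {
  ds <- make_tiny_cohort()
  out <- tempfile(fileext = ".vcf")
  write_vcf(ds, out)
  ds2 <- read_vcf(out)
  expect_equal(ds2$samples, ds$samples)
  expect_equal(ds2$variants, ds$variants)
  expect_equal(unname(ds2$gt), unname(ds$gt))
  expect_equal(unname(ds2$dp), unname(ds$dp))
  expect_equal(unname(ds2$gq), unname(ds$gq))
  # gz round-trip too
  out_gz <- tempfile(fileext = ".vcf.gz")
  write_vcf(ds, out_gz)
  ds3 <- read_vcf(out_gz)
  expect_equal(unname(ds3$gt), unname(ds$gt))
})

test_that("round-trip preserves an empty callset and missing genotypes", {
  ds <- make_tiny_cohort()
  empty <- ds[integer(0), ]
  out <- tempfile(fileext = ".vcf")
  write_vcf(empty, out)
  back <- read_vcf(out)
  expect_equal(nrow(back$variants), 0)
  expect_equal(back$samples, ds$samples)
})

test_that("array genotype reading applies the GenCall cutoff", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(
    sample = "S1", chrom = "1", pos = 1:5, ref = "A", alt = "G",
    genotype = c("HOM_REF", "HET", "HOM_ALT", "HET", "HOM_REF"),
    gencall_score = c(0.9, 0.5, 0.31, 0.29, 0.1)
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  suppressMessages(arr <- read_array_genotypes(path, min_gencall = 0.3))
  expect_equal(nrow(arr), 3)
  expect_true(all(arr$gencall_score >= 0.3))
  arr_all <- read_array_genotypes(path, min_gencall = 0)
  expect_equal(nrow(arr_all), 5)
})

test_that("array reading rejects bad tokens and duplicate keys", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(sample = "S1", chrom = "1", pos = c(1, 1), ref = "A",
                   alt = "G", genotype = c("HET", "HET"),
                   gencall_score = 0.9)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_array_genotypes(path), "duplicate")
  df$pos <- c(1, 2); df$genotype <- c("HET", "BOTH")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_array_genotypes(path), "genotype token")
})

test_that("site sets deduplicate and enforce 1-based positions", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(chrom = "1", pos = c(10, 20, 10, 30), ref = "A",
                   alt = "G")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  ss <- read_site_set(path)
  expect_equal(nrow(ss), 3)
  write.table(df[0, ], path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(nrow(read_site_set(path)), 0)
  df$pos[1] <- 0
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_site_set(path), "1-based")
})

test_that("batch assignment partitions the genotype matrix", {
  ds <- make_tiny_cohort()
  ds6 <- ds
  # widen to 6 samples by duplicating columns under new names
  ds6 <- cohort_dataset(paste0("S", 1:6), ds$variants,
                        gt = cbind(ds$gt, ds$gt),
                        dp = cbind(ds$dp, ds$dp),
                        gq = cbind(ds$gq, ds$gq))
  batch <- setNames(rep(c("A", "B"), each = 3), paste0("S", 1:6))
  parts <- assign_batches(ds6, batch)
  expect_named(parts, c("A", "B"))
  expect_equal(lengths(lapply(parts, `[[`, "samples")),
               c(A = 3L, B = 3L))
  expect_equal(variant_keys(parts$A), variant_keys(ds6))
  # multiset union of per-batch columns equals the original matrix
  rebuilt <- cbind(parts$A$gt, parts$B$gt)[, ds6$samples]
  expect_equal(rebuilt, ds6$gt)

  expect_error(assign_batches(ds6, batch[-1]), "missing from batch")
  expect_error(assign_batches(ds6, c(batch, SX = "A")), "unknown sample")
  one <- assign_batches(ds6, setNames(rep("A", 6), paste0("S", 1:6)))
  expect_equal(length(one), 1)
  expect_equal(one$A$gt, ds6$gt)
})

test_that("cohort validation enforces the data model invariants", {
  v <- data.frame(chrom = "1", pos = 1L, ref = "A", alt = "A",
                  vqsr_pass = TRUE)
  expect_error(cohort_dataset("S1", v, gt = matrix(0L, 1, 1)),
               "must differ")
  v$alt <- "G"
  expect_error(
    cohort_dataset(c("S1", "S1"), rbind(v, v),
                   gt = matrix(0L, 2, 2)), "unique")
  expect_error(
    cohort_dataset("S1", rbind(v, v), gt = matrix(0L, 2, 1)),
    "variant keys")
  expect_error(cohort_dataset("S1", v, gt = matrix(3L, 1, 1)),
               "dosages")
})
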