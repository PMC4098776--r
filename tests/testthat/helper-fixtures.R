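# Fixtures are built in code at test time.

# A hand-written VCF exercising: biallelic SNVs, an indel, a triallelic
# SNV, a half-missing genotype, absent DP/GQ fields and a VQSR-fail
# FILTER value.
write_fixture_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("1", "100", ".", "A", "G", "50", "PASS", ".", "GT:DP:GQ",
          "0/1:12:30", "1/1:8:20", "0/0:40:99", sep = "\t"),
    paste("1", "200", "rs1", "C", "T", "50",
          "VQSRTrancheSNP99.90to100.00", ".", "GT:DP:GQ",
          "0/0:10:25", "./.:.:.", "0/1:7:18", sep = "\t"),
    paste("1", "300", ".", "G", "GA", "50", "PASS", ".", "GT:DP:GQ",
          "0/1:10:30", "0/0:10:30", "0/0:10:30", sep = "\t"),
    paste("1", "400", ".", "T", "A,C", "50", "PASS", ".", "GT:DP:GQ",
          "1/2:15:40", "0/1:9:22", "0/2:11:33", sep = "\t")
  )
  writeLines(lines, path)
  path
}

# Tiny in-memory cohort with explicit values.
make_tiny_cohort <- function() {
  variants <- data.frame(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
    vqsr_pass = c(TRUE, TRUE, FALSE, TRUE)
  )
  gt <- matrix(c(
    0L, 1L, 2L,
    1L, NA, 0L,
    0L, 0L, 1L,
    2L, 1L, NA
  ), nrow = 4, byrow = TRUE)
  dp <- matrix(10L, 4, 3)
  gq <- matrix(c(
    20L, 30L, 40L,
    99L, NA, 35L,
    15L, 50L, 22L,
    60L, 45L, NA
  ), nrow = 4, byrow = TRUE)
  cohort_dataset(c("S1", "S2", "S3"), variants, gt = gt, dp = dp, gq = gq)
}

# Small simulated cohort shared by several tests (cached per session).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_cohort(sim_config(
        n_samples = 60, n_variants = 3000, seed = 101L))
    }
    cache
  }
})

# Independent HWE oracle: direct Levene-Haldane probabilities through
# log-factorials (no recurrence), same plain-tail definition.
hwe_oracle <- function(a, h, b) {
  n <- a + h + b
  rare <- min(2 * a + h, 2 * b + h)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, 2)
  lp <- lfactorial(n) - lfactorial((rare - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (rare + hs) / 2) + hs * log(2) +
    lfactorial(rare) + lfactorial(2 * n - rare) - lfactorial(2 * n)
  p <- exp(lp)
  p <- p / sum(p)
  obs <- p[match(h, hs)]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Independent hypergeometric upper-tail oracle by term enumeration.
tv_enrichment_oracle <- function(ti, tv, removed, k) {
  js <- k:min(removed, tv)
  js <- js[removed - js <= ti]
  sum(exp(lchoose(tv, js) + lchoose(ti, removed - js) -
            lchoose(ti + tv, removed)))
}
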