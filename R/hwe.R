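# Exact test for Hardy-Weinberg equilibrium on diploid genotype counts.
#
# Conditional on the minor-allele count and the number of diploids, the
# heterozygote count under HWE follows the Levene-Haldane distribution.
# The exact p-value sums the probabilities of all achievable heterozygote
# counts whose probability does not exceed that of the observed count
# (plain exact tail, no mid-p adjustment) — the behaviour of the exact
# test used by standard variant-filtering tools, preferred over the
# chi-square approximation which is anti-conservative at rare minor
# allele frequencies, exactly where exome filtering operates.

# Relative tolerance for "no more probable than observed". Probabilities
# of distinct heterozygote counts are compared through floating point;
# a small relative slack keeps the tie rule stable.
.hwe_tie_tol <- 1e-7

#' Hardy-Weinberg exact test p-value
#'
#' @param n_hom_ref,n_het,n_hom_alt Genotype counts at one biallelic site
#'   (non-missing genotypes only). `n_hom_ref` may also be a 3-column
#'   matrix of counts (as from [genotype_counts()]), in which case a
#'   vector of p-values is returned.
#' @return Exact p-value(s) in (0, 1]. A monomorphic site has a single
#'   achievable configuration and p = 1.
#' @export
hwe_exact_pvalue <- function(n_hom_ref, n_het = NULL, n_hom_alt = NULL) {
  if (is.matrix(n_hom_ref)) {
    m <- n_hom_ref
    return(vapply(seq_len(nrow(m)), function(i) {
      hwe_exact_pvalue(m[i, 1], m[i, 2], m[i, 3])
    }, numeric(1)))
  }
  a <- n_hom_ref; h <- n_het; b <- n_hom_alt
  if (any(c(a, h, b) < 0)) stop("genotype counts must be >= 0", call. = FALSE)
  n <- a + h + b
  if (n < 1) stop("no genotypes (all counts zero)", call. = FALSE)
  rare <- min(2 * a + h, 2 * b + h)   # minor-allele count
  if (rare == 0) return(1)

  probs <- hwe_het_distribution(rare, n)
  obs <- probs[as.character(h)]
  sum(probs[probs <= obs * (1 + .hwe_tie_tol)])
}

# Probability mass over achievable heterozygote counts given `rare` minor
# alleles among `n` diploids, by the stable two-sided recurrence from the
# modal heterozygote count (normalized at the end). Names are the het
# counts.
hwe_het_distribution <- function(rare, n) {
  common <- 2 * n - rare
  hs <- seq.int(rare %% 2, min(rare, common), by = 2)
  # modal het count, matched to achievable parity
  mid <- floor(rare * common / (2 * n))
  if (mid %% 2 != rare %% 2) mid <- mid + 1
  mid <- min(max(mid, min(hs)), max(hs))

  val <- stats::setNames(numeric(length(hs)), hs)
  val[as.character(mid)] <- 1
  # going down: P(h-2) = P(h) * h*(h-1) / (4 * (nr+1) * (nc+1))
  h <- mid
  while (h - 2 >= min(hs)) {
    nr <- (rare - h) / 2      # rare-allele homozygotes at h
    nc <- n - nr - h          # common-allele homozygotes at h
    val[as.character(h - 2)] <-
      val[as.character(h)] * h * (h - 1) / (4 * (nr + 1) * (nc + 1))
    h <- h - 2
  }
  # going up: P(h+2) = P(h) * 4*nr*nc / ((h+2)*(h+1))
  h <- mid
  while (h + 2 <= max(hs)) {
    nr <- (rare - h) / 2
    nc <- n - nr - h
    val[as.character(h + 2)] <-
      val[as.character(h)] * 4 * nr * nc / ((h + 2) * (h + 1))
    h <- h + 2
  }
  val / sum(val)
}

#' Remove variants deviating from Hardy-Weinberg equilibrium
#'
#' Tests every variant with at least one non-missing genotype with the
#' exact test and removes those with `p <= alpha / N`, where N is the
#' number of testable variants in this dataset (Bonferroni correction
#' scoped to the dataset being filtered — per batch when filtering is
#' batched). Run after genotype masking so counts reflect surviving
#' genotypes.
#'
#' @param dataset A [cohort_dataset()].
#' @param alpha Uncorrected significance level (default 0.05).
#' @return List with `dataset` (survivors), `removed` (removed variant
#'   rows, with their p-values), `n_tested` and `threshold`.
#' @export
hwe_filter <- function(dataset, alpha = 0.05) {
  cnt <- genotype_counts(dataset)
  testable <- rowSums(cnt) > 0
  n_tested <- sum(testable)
  p <- rep(NA_real_, nrow(cnt))
  if (n_tested > 0) {
    p[testable] <- hwe_exact_pvalue(cnt[testable, , drop = FALSE])
  }
  threshold <- if (n_tested > 0) alpha / n_tested else 0
  drop <- !is.na(p) & p <= threshold
  removed <- dataset$variants[drop, , drop = FALSE]
  removed$hwe_p <- p[drop]
  rownames(removed) <- NULL
  list(dataset = dataset[!drop, ], removed = removed,
       n_tested = n_tested, threshold = threshold)
}
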