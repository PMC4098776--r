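# Genotype-level filters: mask individual genotypes whose read depth (DP)
# or genotype quality (GQ) falls below threshold. Masking (rather than
# record deletion) is deliberate: downstream call-rate computations must
# see masked genotypes as missing.

#' Probability that a true heterozygote looks monoallelic
#'
#' Under a two-tailed binomial model where each allele of a heterozygous
#' genotype has a 50% chance of being drawn in each read, the probability
#' that all `dp` reads carry the same allele is `2 * (1/2)^dp` (capped at
#' 1). This is the rationale for the default depth threshold: DP >= 8
#' brings the probability below 1%, and DP >= 11 below 0.1%.
#'
#' @param dp Read depth, integer >= 1 (vectorized).
#' @return Probability in (0, 1].
#' @export
het_mono_probability <- function(dp) {
  if (any(dp < 1)) stop("dp must be >= 1", call. = FALSE)
  pmin(1, 2 * 0.5^dp)
}

#' Genotype accuracy implied by a Phred-scaled quality
#'
#' A Phred-scaled genotype quality GQ corresponds to an error probability
#' of `10^(-GQ/10)`, i.e. an accuracy of `1 - 10^(-GQ/10)`. GQ = 20 gives
#' 99% accuracy (the default genotype-quality threshold); GQ = 30 gives
#' 99.9%.
#'
#' @param gq Phred-scaled genotype quality, >= 0 (vectorized).
#' @return Probability in `[0, 1)`.
#' @export
phred_accuracy <- function(gq) {
  if (any(gq < 0)) stop("gq must be >= 0", call. = FALSE)
  1 - 10^(-gq / 10)
}

#' Mask low-quality genotypes
#'
#' Sets to missing every called genotype whose DP or GQ is below the
#' corresponding threshold. A threshold of 0 disables that filter; with a
#' positive threshold, a called genotype whose field is absent fails the
#' filter (conservative). The variant set is unchanged — masked genotypes
#' simply become missing, which is how the call-rate filter later sees
#' them.
#'
#' @param dataset A [cohort_dataset()].
#' @param min_dp Minimum read depth (default 8, the <1% monoallelic-
#'   appearance criterion; see [het_mono_probability()]).
#' @param min_gq Minimum genotype quality (default 20, i.e. 99% accuracy;
#'   see [phred_accuracy()]).
#' @return List with elements `dataset` (masked) and `report`, a one-row
#'   data frame per genotype class (`nonref`, `ref`) with columns
#'   `n_genotypes_before`, `n_masked_dp`, `n_masked_gq`, `n_masked_total`
#'   (union of the two, not their sum).
#' @export
apply_genotype_filters <- function(dataset, min_dp = 8, min_gq = 20) {
  if (min_dp < 0 || min_gq < 0) {
    stop("thresholds must be >= 0", call. = FALSE)
  }
  gt <- dataset$gt
  called <- !is.na(gt)
  fail_dp <- if (min_dp > 0) {
    called & (is.na(dataset$dp) | dataset$dp < min_dp)
  } else {
    called & FALSE
  }
  fail_gq <- if (min_gq > 0) {
    called & (is.na(dataset$gq) | dataset$gq < min_gq)
  } else {
    called & FALSE
  }
  fail <- fail_dp | fail_gq
  nonref <- called & gt > 0L

  report <- data.frame(
    class = c("nonref", "ref", "all"),
    n_genotypes_before = c(sum(nonref), sum(called & !nonref), sum(called)),
    n_masked_dp = c(sum(fail_dp & nonref), sum(fail_dp & !nonref),
                    sum(fail_dp)),
    n_masked_gq = c(sum(fail_gq & nonref), sum(fail_gq & !nonref),
                    sum(fail_gq)),
    n_masked_total = c(sum(fail & nonref), sum(fail & !nonref), sum(fail))
  )
  dataset$gt[fail] <- NA_integer_
  list(dataset = dataset, report = report)
}
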