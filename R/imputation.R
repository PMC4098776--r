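# Filters for imputed genotype panels. Imputed genotypes carry a GQ from
# the imputation engine's genotype probabilities and each variant carries
# the engine's allelic R-squared. GQ masking at the same 99%-confidence
# threshold used for sequenced genotypes, followed by pruning of
# uninformative variants, is compared against the conventional hard
# R-squared > 0.3 cutoff.

#' Construct an imputed genotype panel
#'
#' Same layout as a [cohort_dataset()] plus a per-variant `r2` column
#' (the imputation engine's allelic R-squared in `[0, 1]`). Depth is not
#' meaningful for imputed genotypes and is absent.
#'
#' @param samples Character vector of sample identifiers.
#' @param variants Data frame with chrom/pos/ref/alt/vqsr_pass and `r2`
#'   columns (`vqsr_pass` may be omitted; imputed panels default to TRUE).
#' @param gt,gq Integer matrices as in [cohort_dataset()].
#' @return An object of class `imputed_panel` (also a `cohort_dataset`).
#' @export
imputed_panel <- function(samples, variants, gt, gq) {
  if (is.null(variants$vqsr_pass)) variants$vqsr_pass <- TRUE
  r2 <- as.numeric(variants$r2)
  if (any(is.na(r2)) || any(r2 < 0) || any(r2 > 1)) {
    stop("r2 must be in [0, 1]", call. = FALSE)
  }
  x <- cohort_dataset(samples, variants, gt = gt, gq = gq)
  x$variants$r2 <- r2
  class(x) <- c("imputed_panel", class(x))
  x
}

#' Mask low-quality imputed genotypes
#'
#' Sets imputed genotypes with GQ below threshold to missing. GQ >= 20
#' (99% genotype confidence) is the default, the same criterion used for
#' sequenced genotypes.
#'
#' @param panel An [imputed_panel()].
#' @param min_gq Minimum genotype quality (>= 0); 0 disables the filter.
#' @return List with `panel` (masked) and `report` (removals split by
#'   reference / non-reference genotype class).
#' @export
filter_imputed_genotypes <- function(panel, min_gq = 20) {
  if (min_gq < 0) stop("min_gq must be >= 0", call. = FALSE)
  called <- !is.na(panel$gt)
  fail <- if (min_gq > 0) {
    called & (is.na(panel$gq) | panel$gq < min_gq)
  } else {
    called & FALSE
  }
  nonref <- called & panel$gt > 0L
  report <- data.frame(
    class = c("nonref", "ref", "all"),
    n_genotypes_before = c(sum(nonref), sum(called & !nonref), sum(called)),
    n_masked = c(sum(fail & nonref), sum(fail & !nonref), sum(fail))
  )
  panel$gt[fail] <- NA_integer_
  list(panel = panel, report = report)
}

#' Classify imputed variants after GQ filtering
#'
#' A variant with no non-missing genotype left is `no_genotype`; one
#' whose non-missing genotypes are all homozygous for the same allele
#' (all HOM_REF or all HOM_ALT) is `monoallelic`; anything else is
#' `polymorphic`. Run after [filter_imputed_genotypes()].
#'
#' @param panel An [imputed_panel()].
#' @return Character vector, one class per variant.
#' @export
classify_imputed_variants <- function(panel) {
  cnt <- genotype_counts(panel)
  total <- rowSums(cnt)
  mono <- (cnt[, "n_het"] == 0) &
    (cnt[, "n_hom_ref"] == 0 | cnt[, "n_hom_alt"] == 0)
  ifelse(total == 0, "no_genotype",
         ifelse(mono, "monoallelic", "polymorphic"))
}

#' Prune uninformative imputed variants
#'
#' Removes `monoallelic` and `no_genotype` variants (see
#' [classify_imputed_variants()]) — sites that carry no genotype
#' information after GQ filtering.
#'
#' @param panel An [imputed_panel()], already GQ-filtered.
#' @return List with `panel` (polymorphic survivors) and `report`, a data
#'   frame of per-class counts and mean R-squared.
#' @export
prune_uninformative <- function(panel) {
  cls <- classify_imputed_variants(panel)
  report <- do.call(rbind, lapply(
    c("polymorphic", "monoallelic", "no_genotype"), function(k) {
      sel <- cls == k
      data.frame(class = k, n_variants = sum(sel),
                 mean_r2 = if (any(sel)) mean(panel$variants$r2[sel])
                           else NA_real_)
    }))
  list(panel = panel[cls == "polymorphic", ], report = report)
}

#' Hard R-squared cutoff filter
#'
#' The conventional genome-wide-association baseline: retain variants
#' with imputation R-squared strictly greater than the cutoff (default
#' 0.3). Genotypes are untouched.
#'
#' @param panel An [imputed_panel()].
#' @param min_r2 Cutoff in `[0, 1]`; variants with `r2 <= min_r2` are
#'   removed.
#' @return List with `panel` (survivors) and `report` (counts).
#' @export
r2_threshold_filter <- function(panel, min_r2 = 0.3) {
  if (min_r2 < 0 || min_r2 > 1) {
    stop("min_r2 must be in [0, 1]", call. = FALSE)
  }
  keep <- panel$variants$r2 > min_r2
  report <- data.frame(n_input = length(keep), n_removed = sum(!keep),
                       n_retained = sum(keep))
  list(panel = panel[keep, ], report = report)
}
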