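# Sequencing-versus-array genotype concordance.
#
# The array genotypes are the gold standard. True negatives are identical
# homozygous-reference matches; true positives identical heterozygous or
# homozygous-alternate matches. A sequencing call missing at least one
# alternate allele relative to the array is a false negative; one with at
# least one extra alternate allele a false positive (alt-allele dosage
# comparison, which makes the four classes exhaustive over the nine
# non-missing genotype pairs). Missing sequencing genotypes are excluded
# from the comparison — this is what lets genotype filters "remove"
# discordant genotypes.

#' Classify one sequencing/array genotype pair
#'
#' @param wes Sequencing genotype: `HOM_REF`, `HET`, `HOM_ALT`, `MISSING`
#'   (or dosage 0/1/2/NA). Vectorized.
#' @param array Array genotype: `HOM_REF`, `HET`, `HOM_ALT` (or dosage).
#' @return Character vector over `TP`, `TN`, `FP`, `FN`, `EXCLUDED`.
#' @export
classify_genotype_pair <- function(wes, array) {
  to_dose <- function(g, allow_missing) {
    if (is.character(g) || is.factor(g)) {
      code <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L, MISSING = NA_integer_)
      g <- as.character(g)
      ok <- g %in% names(code)
      if (!all(ok)) stop("unknown genotype token", call. = FALSE)
      g <- unname(code[g])
    }
    g <- as.integer(g)
    if (!allow_missing && any(is.na(g))) {
      stop("array genotype cannot be missing", call. = FALSE)
    }
    g
  }
  w <- to_dose(wes, allow_missing = TRUE)
  a <- to_dose(array, allow_missing = FALSE)
  out <- rep("EXCLUDED", length(w))
  cmp <- !is.na(w)
  out[cmp & w == a & a == 0L] <- "TN"
  out[cmp & w == a & a > 0L] <- "TP"
  out[cmp & w < a] <- "FN"
  out[cmp & w > a] <- "FP"
  out
}

#' Concordance table between a cohort and array genotypes
#'
#' Compares every (sample, site) present in both sources; sites absent
#' from the sequencing dataset are not compared, and shared positions
#' whose ref/alt alleles disagree between sources are excluded with a
#' message (no allele harmonization is attempted).
#'
#' @param dataset A [cohort_dataset()].
#' @param array An [array_genotypes()] object.
#' @return A list of class `concordance_table` with counts `tp`, `tn`,
#'   `fp`, `fn`, `nonref_concordant`, `nonref_discordant`,
#'   `ref_concordant`, `ref_discordant` and `n_compared`. Non-reference /
#'   reference refer to the array genotype class.
#' @export
concordance_report <- function(dataset, array) {
  vk <- variant_keys(dataset)
  ak <- paste(array$chrom, array$pos, array$ref, array$alt, sep = ":")
  vi <- match(ak, vk)
  # allele mismatch: position shared but ref/alt differ
  pos_key <- paste(dataset$variants$chrom, dataset$variants$pos, sep = ":")
  apos <- paste(array$chrom, array$pos, sep = ":")
  mismatch <- is.na(vi) & apos %in% pos_key
  if (any(mismatch)) {
    message(sum(mismatch),
            " array record(s) with allele mismatch excluded")
  }
  si <- match(array$sample, dataset$samples)
  use <- !is.na(vi) & !is.na(si)
  w <- dataset$gt[cbind(vi[use], si[use])]
  a <- array$genotype[use]
  cls <- classify_genotype_pair(w, a)
  keep <- cls != "EXCLUDED"
  cls <- cls[keep]; a <- a[keep]
  tab <- function(x) sum(cls == x)
  nonref <- a > 0L
  structure(list(
    tp = tab("TP"), tn = tab("TN"), fp = tab("FP"), fn = tab("FN"),
    nonref_concordant = sum(cls == "TP"),
    nonref_discordant = sum(nonref & cls != "TP"),
    ref_concordant = sum(cls == "TN"),
    ref_discordant = sum(!nonref & cls != "TN"),
    n_compared = length(cls)
  ), class = "concordance_table")
}

#' Concordance table from explicit counts
#'
#' Builds a `concordance_table` directly from published or externally
#' computed counts, for evaluating [metrics_from_counts()] and
#' [removal_fractions()] on reported tables.
#'
#' @param tp,tn,fp,fn Classification counts.
#' @param nonref_discordant,ref_discordant Discordant-comparison counts
#'   against array non-reference / reference genotypes; default to `fn`
#'   and `fp` (the common case where all non-reference discordance is
#'   missing alternate alleles).
#' @return A `concordance_table`.
#' @export
concordance_counts <- function(tp, tn, fp, fn,
                               nonref_discordant = fn,
                               ref_discordant = fp) {
  structure(list(
    tp = tp, tn = tn, fp = fp, fn = fn,
    nonref_concordant = tp, nonref_discordant = nonref_discordant,
    ref_concordant = tn, ref_discordant = ref_discordant,
    n_compared = tp + tn + fp + fn
  ), class = "concordance_table")
}

#' @export
#' @method print concordance_table
print.concordance_table <- function(x, ...) {
  cat(sprintf(
    "<concordance_table> n=%d  TP=%d TN=%d FP=%d FN=%d\n", x$n_compared,
    x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Concordance and accuracy metrics from a table
#'
#' Sensitivity is `TP / (TP + FN)` and specificity `TN / (TN + FP)`;
#' non-reference concordance equals sensitivity and reference concordance
#' equals specificity under the alt-dosage classification.
#'
#' @param table A `concordance_table`.
#' @return List with `sensitivity`, `specificity`, `nonref_concordance`
#'   and `ref_concordance`; a metric whose denominator is zero is NA.
#' @export
metrics_from_counts <- function(table) {
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(table$tp, table$tp + table$fn)
  spec <- frac(table$tn, table$tn + table$fp)
  list(sensitivity = sens, specificity = spec,
       nonref_concordance = sens, ref_concordance = spec)
}

#' Fractions of concordant/discordant genotypes removed by a filter
#'
#' Compares the comparison tables before and after a filtering step: a
#' good genotype filter removes a large fraction of the discordant
#' comparisons while retaining the concordant ones.
#'
#' @param before,after `concordance_table`s computed against the same
#'   array genotypes; `after` counts must not exceed `before` counts.
#' @return List with `pct_concordant_removed`, `pct_discordant_removed`
#'   (non-reference class) and `pct_ref_concordant_removed`,
#'   `pct_ref_discordant_removed` (reference class), as fractions; NA
#'   where the before-count is zero.
#' @export
removal_fractions <- function(before, after) {
  fields <- c("nonref_concordant", "nonref_discordant",
              "ref_concordant", "ref_discordant")
  for (f in fields) {
    if (after[[f]] > before[[f]]) {
      stop("'after' counts exceed 'before' counts (", f, ")",
           call. = FALSE)
    }
  }
  frac <- function(f) {
    if (before[[f]] > 0) (before[[f]] - after[[f]]) / before[[f]]
    else NA_real_
  }
  list(
    pct_concordant_removed = frac("nonref_concordant"),
    pct_discordant_removed = frac("nonref_discordant"),
    pct_ref_concordant_removed = frac("ref_concordant"),
    pct_ref_discordant_removed = frac("ref_discordant")
  )
}
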