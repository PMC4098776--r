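# Transition/transversion accounting and the hypergeometric test for
# transversion enrichment among removed variants. Ti/Tv is a ratio of
# variant counts (each site counts once, regardless of call rate);
# ~0.5 is the random expectation, 2.8-3.0 the expectation for high
# quality exome variant sets.

#' Is a substitution a transition?
#'
#' Transitions are purine-purine (A<->G) or pyrimidine-pyrimidine
#' (C<->T) exchanges; everything else is a transversion.
#'
#' @param ref,alt Single nucleotides in A/C/G/T, `ref != alt`
#'   (vectorized).
#' @return Logical vector.
#' @export
is_transition <- function(ref, alt) {
  nt <- c("A", "C", "G", "T")
  if (!all(ref %in% nt) || !all(alt %in% nt)) {
    stop("ref and alt must be nucleotides in A/C/G/T", call. = FALSE)
  }
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

#' Ti/Tv summary stratified by site-set membership
#'
#' Counts transitions and transversions over all variants and within the
#' known (in the known set), novel (not in the known set) and truth
#' strata.
#'
#' @param variants A [cohort_dataset()] or a variant data frame with
#'   chrom/pos/ref/alt columns.
#' @param known,truth [site_set()]s (NULL for empty).
#' @return A data frame of class `titv_summary` with columns `stratum`
#'   (all/known/novel/truth), `n_ti`, `n_tv` and `ratio` (NA when
#'   `n_tv = 0`).
#' @export
titv_summary <- function(variants, known = NULL, truth = NULL) {
  v <- if (is.data.frame(variants)) variants else variants$variants
  ti <- if (nrow(v) > 0) is_transition(v$ref, v$alt) else logical(0)
  in_known <- in_site_set(v, known)
  in_truth <- in_site_set(v, truth)
  strata <- list(all = rep(TRUE, nrow(v)), known = in_known,
                 novel = !in_known, truth = in_truth)
  out <- do.call(rbind, lapply(names(strata), function(s) {
    sel <- strata[[s]]
    n_ti <- sum(ti & sel); n_tv <- sum(!ti & sel)
    data.frame(stratum = s, n_ti = n_ti, n_tv = n_tv,
               ratio = if (n_tv > 0) n_ti / n_tv else NA_real_)
  }))
  structure(out, class = c("titv_summary", "data.frame"))
}

#' Transversion-enrichment p-value for a removed variant set
#'
#' One-tailed hypergeometric upper-tail probability that a uniform draw
#' of `n_removed` variants from the pre-filter pool contains at least
#' `n_tv_removed` transversions — the test of whether a filter removes
#' transversions preferentially (as a quality-improving filter should).
#'
#' @param n_ti_before,n_tv_before Transition/transversion counts in the
#'   pre-filter pool.
#' @param n_removed Number of variants the filter removed.
#' @param n_tv_removed Number of transversions among the removed.
#' @return Upper-tail probability `P(X >= n_tv_removed)`.
#' @export
tv_enrichment_pvalue <- function(n_ti_before, n_tv_before, n_removed,
                                 n_tv_removed) {
  if (n_removed > n_ti_before + n_tv_before ||
      n_tv_removed > min(n_removed, n_tv_before) ||
      n_removed - n_tv_removed > n_ti_before ||
      any(c(n_ti_before, n_tv_before, n_removed, n_tv_removed) < 0)) {
    stop("inconsistent transition/transversion counts", call. = FALSE)
  }
  stats::phyper(n_tv_removed - 1, m = n_tv_before, n = n_ti_before,
                k = n_removed, lower.tail = FALSE)
}

#' Fraction of truth-set variants retained by a filtering step
#'
#' @param before,after Variant collections ([cohort_dataset()] or variant
#'   data frames); `after` must be a subset of `before` by key.
#' @param truth A [site_set()] of true variants.
#' @return Fraction of `before`'s truth variants still present in
#'   `after`; 1 (with a message) when `before` contains no truth variant.
#' @export
truth_retention <- function(before, after, truth) {
  kb <- variant_keys(before)
  ka <- variant_keys(after)
  if (!all(ka %in% kb)) {
    stop("'after' must be a subset of 'before'", call. = FALSE)
  }
  kt <- variant_keys(truth)
  n_before <- sum(kb %in% kt)
  if (n_before == 0) {
    message("no truth variants in 'before'; retention reported as 1")
    return(1)
  }
  sum(ka %in% kt) / n_before
}
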