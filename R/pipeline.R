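# End-to-end orchestration: genotype filters then variant filters, run
# per processing batch and merged, or pooled ("unbatched"), plus the
# comparison reports between the two strategies and between filter
# orders.

#' Pipeline configuration
#'
#' @param thresholds A [filter_thresholds()] object.
#' @param batch Named character vector mapping samples to batch labels
#'   (or a batch-table path); NULL for a single implicit batch.
#' @param known,truth [site_set()]s for Ti/Tv stratification (optional).
#' @param seed Integer seed for any subsampling (the cascade itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = filter_thresholds(),
                            batch = NULL, known = NULL, truth = NULL,
                            seed = 1L) {
  structure(list(thresholds = thresholds, batch = batch, known = known,
                 truth = truth, seed = seed),
            class = "pipeline_config")
}

run_cascade <- function(dataset, thresholds) {
  gf <- apply_genotype_filters(dataset, min_dp = thresholds$min_dp,
                               min_gq = thresholds$min_gq)
  vf <- apply_variant_filters(gf$dataset, thresholds)
  list(dataset = vf$dataset,
       genotype_report = gf$report, variant_report = vf$report)
}

#' Run the filtering cascade on the pooled cohort
#'
#' Applies genotype masking followed by the variant-filter cascade once
#' to all samples together.
#'
#' @param dataset A [cohort_dataset()].
#' @param config A [pipeline_config()].
#' @return List with `dataset` (survivors), `genotype_report` and
#'   `variant_report`.
#' @export
run_unbatched_pipeline <- function(dataset, config = pipeline_config()) {
  run_cascade(dataset, config$thresholds)
}

#' Run the filtering cascade per batch and merge survivors
#'
#' Splits the cohort by batch, applies the full cascade to each batch
#' independently, and merges: the output contains the union of variant
#' keys passing in at least one batch. For each merged variant, genotypes
#' come from the batches where it passed (post-masking values); samples
#' in batches where it failed or was absent are set missing. Filtering
#' per batch is what rescues variants whose pooled call rate is dragged
#' below threshold by batches that never targeted the site.
#'
#' @param dataset A [cohort_dataset()].
#' @param config A [pipeline_config()]; its `batch` element (or the
#'   dataset's own batch assignment) must cover every sample.
#' @return List with `dataset` (merged survivors, samples in original
#'   roster order), `batch_results` (per-batch cascade results) and
#'   `passed_in` (named list: batch labels in which each merged variant
#'   key passed).
#' @export
run_batched_pipeline <- function(dataset, config = pipeline_config()) {
  batch <- config$batch
  if (is.null(batch)) batch <- dataset$batch
  if (is.null(batch)) {
    stop("no batch assignment in config or dataset", call. = FALSE)
  }
  parts <- assign_batches(dataset, batch)
  if (any(vapply(parts, function(d) length(d$samples), integer(1)) == 0)) {
    stop("batch with zero samples", call. = FALSE)
  }
  results <- lapply(parts, run_cascade, thresholds = config$thresholds)

  keys_by_batch <- lapply(results, function(r) variant_keys(r$dataset))
  all_keys <- unique(unlist(keys_by_batch, use.names = FALSE))
  # merged variants keep the input's variant order
  in_keys <- variant_keys(dataset)
  keep <- in_keys %in% all_keys
  merged <- dataset[keep, ]
  mk <- in_keys[keep]

  # start all-missing; fill per batch where the variant passed
  merged$gt[] <- NA_integer_
  for (b in names(results)) {
    rb <- results[[b]]
    rows <- match(keys_by_batch[[b]], mk)
    cols <- match(rb$dataset$samples, merged$samples)
    merged$gt[rows, cols] <- rb$dataset$gt
    merged$dp[rows, cols] <- rb$dataset$dp
    merged$gq[rows, cols] <- rb$dataset$gq
  }
  passed_in <- lapply(stats::setNames(mk, mk), function(k) {
    names(results)[vapply(keys_by_batch, function(ks) k %in% ks,
                          logical(1))]
  })
  list(dataset = merged, batch_results = results, passed_in = passed_in)
}

#' Compare batched and unbatched filtering outcomes
#'
#' Computes the variant sets unique to each strategy (symmetric
#' difference by key) and, for each unique set, its size, Ti/Tv summary
#' and — when an array gold standard is supplied — its concordance table
#' restricted to those sites.
#'
#' @param batched,unbatched Filtered [cohort_dataset()]s derived from the
#'   same input cohort.
#' @param known A [site_set()] for Ti/Tv stratification.
#' @param array Optional [array_genotypes()].
#' @return List of class `batch_comparison` with elements
#'   `batched_unique` and `unbatched_unique`, each a list with `n`,
#'   `keys`, `titv` and (optionally) `concordance`.
#' @export
compare_batched_unbatched <- function(batched, unbatched, known = NULL,
                                      array = NULL) {
  kb <- variant_keys(batched)
  ku <- variant_keys(unbatched)
  one_side <- function(ds, unique_keys) {
    sel <- variant_keys(ds) %in% unique_keys
    d <- ds[sel, ]
    out <- list(n = sum(sel), keys = variant_keys(d),
                titv = titv_summary(d, known = known))
    if (!is.null(array)) out$concordance <- concordance_report(d, array)
    out
  }
  structure(list(
    batched_unique = one_side(batched, setdiff(kb, ku)),
    unbatched_unique = one_side(unbatched, setdiff(ku, kb))
  ), class = "batch_comparison")
}

#' Compare the two VQSR filter orders
#'
#' Runs the cascade with the VQSR verdict applied after the manual
#' variant filters and with it applied before, on the same input, and
#' reports survivor counts, Ti/Tv per order, the extra variants one
#' order removes relative to the other, and the transversion-enrichment
#' p-value of those extra removals against the input pool.
#'
#' @param dataset A [cohort_dataset()] (unfiltered genotypes; the
#'   genotype filters in `config$thresholds` are applied first).
#' @param config A [pipeline_config()].
#' @return List with per-order results (`after_manual`, `before_manual`:
#'   `n_variants`, `titv`), `extra_removed_by_after` /
#'   `extra_removed_by_before` (keys), and `tv_enrichment_p` for the
#'   order that removes more variants (NA when neither removes extra
#'   variants).
#' @export
compare_filter_orders <- function(dataset, config = pipeline_config()) {
  th <- config$thresholds
  run_order <- function(pos) {
    th$vqsr_position <- pos
    run_cascade(dataset, th)$dataset
  }
  d_after <- run_order("after_manual")
  d_before <- run_order("before_manual")
  ka <- variant_keys(d_after); kb <- variant_keys(d_before)
  extra_after <- setdiff(kb, ka)    # removed by after_manual, kept by before
  extra_before <- setdiff(ka, kb)

  ti <- is_transition(dataset$variants$ref, dataset$variants$alt)
  pool_keys <- variant_keys(dataset)
  enrich <- function(extra) {
    if (length(extra) == 0) return(NA_real_)
    sel <- pool_keys %in% extra
    tv_enrichment_pvalue(sum(ti), sum(!ti), sum(sel), sum(sel & !ti))
  }
  list(
    after_manual = list(n_variants = length(ka),
                        titv = titv_summary(d_after, known = config$known,
                                            truth = config$truth)),
    before_manual = list(n_variants = length(kb),
                         titv = titv_summary(d_before, known = config$known,
                                             truth = config$truth)),
    extra_removed_by_after = extra_after,
    extra_removed_by_before = extra_before,
    tv_enrichment_p_after = enrich(extra_after),
    tv_enrichment_p_before = enrich(extra_before)
  )
}
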