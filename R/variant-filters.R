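# Site-level filters: average genotype quality, call rate, the upstream
# VQSR verdict, and the combined cascade in a configurable order.

#' Per-variant average genotype quality
#'
#' Arithmetic mean of GQ over the non-missing genotypes of each variant —
#' the sum of individual genotype GQ values divided by the number of
#' genotypes at the site. Computed after genotype masking, so masked
#' genotypes do not contribute.
#'
#' @param dataset A [cohort_dataset()].
#' @return Numeric vector, one value per variant; NA where a variant has
#'   no non-missing genotype (the scalar accessor errors there).
#' @export
average_gq <- function(dataset) {
  called <- !is.na(dataset$gt)
  gq <- ifelse(called, dataset$gq, NA_integer_)
  n <- rowSums(called & !is.na(gq))
  s <- rowSums(gq, na.rm = TRUE)
  out <- ifelse(n > 0, s / n, NA_real_)
  if (nrow(dataset$variants) == 1 && is.na(out)) {
    stop("average GQ undefined: variant has no non-missing genotype",
         call. = FALSE)
  }
  out
}

#' Per-variant call rate
#'
#' Fraction of cohort samples with a non-missing genotype at each variant.
#' The denominator is the full cohort (or batch) sample count; genotypes
#' masked by the genotype filters count as missing.
#'
#' @param dataset A [cohort_dataset()].
#' @return Numeric vector in `[0, 1]`, one value per variant.
#' @export
call_rate <- function(dataset) {
  if (length(dataset$samples) < 1) stop("cohort has no samples", call. = FALSE)
  rowMeans(!is.na(dataset$gt))
}

#' Apply the upstream VQSR verdict
#'
#' Retains variants whose FILTER column marked them as passing VQSR. The
#' recalibration itself is performed upstream (at the recommended 99%
#' sensitivity tranche); only its verdict is consumed here.
#'
#' @param dataset A [cohort_dataset()].
#' @return List with `dataset` (survivors) and `removed` (variant rows).
#' @export
apply_vqsr <- function(dataset) {
  keep <- dataset$variants$vqsr_pass
  removed <- dataset$variants[!keep, , drop = FALSE]
  rownames(removed) <- NULL
  list(dataset = dataset[keep, ], removed = removed)
}

#' Filter thresholds for the variant cascade
#'
#' @param min_dp,min_gq Genotype-level thresholds (defaults 8 and 20; see
#'   [apply_genotype_filters()]).
#' @param hwe_alpha Significance level for the Hardy-Weinberg exact test,
#'   Bonferroni-corrected within the dataset being filtered (default
#'   0.05).
#' @param min_avg_gq Minimum average genotype quality (default 35, the
#'   99%-truth-sensitivity choice).
#' @param min_call_rate Minimum call rate (default 0.88, the
#'   96%-truth-retention choice).
#' @param vqsr_position Where the VQSR verdict is applied relative to the
#'   manual filters: `"after_manual"` (default, the recommended order),
#'   `"before_manual"`, or `"off"`.
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_dp = 8, min_gq = 20, hwe_alpha = 0.05,
                              min_avg_gq = 35, min_call_rate = 0.88,
                              vqsr_position = c("after_manual",
                                                "before_manual", "off")) {
  vqsr_position <- match.arg(vqsr_position)
  if (min_call_rate < 0 || min_call_rate > 1) {
    stop("min_call_rate must be in [0, 1]", call. = FALSE)
  }
  if (hwe_alpha <= 0 || hwe_alpha > 1) {
    stop("hwe_alpha must be in (0, 1]", call. = FALSE)
  }
  structure(list(min_dp = min_dp, min_gq = min_gq, hwe_alpha = hwe_alpha,
                 min_avg_gq = min_avg_gq, min_call_rate = min_call_rate,
                 vqsr_position = vqsr_position),
            class = "filter_thresholds")
}

#' Apply the variant-filter cascade
#'
#' Applies, in order: the Hardy-Weinberg exact-test filter, the
#' average-GQ filter (remove variants with average GQ below
#' `min_avg_gq`), the call-rate filter (remove variants with call rate
#' below `min_call_rate`), and finally the VQSR verdict — applying the
#' verdict after the manual filters is the order that consistently
#' yields the higher Ti/Tv ratio among survivors. Setting
#' `vqsr_position = "before_manual"` applies the verdict first instead.
#' Genotype filters are assumed to have been applied already.
#'
#' @param dataset A [cohort_dataset()].
#' @param thresholds A [filter_thresholds()] object.
#' @return List with `dataset` (survivors) and `report`, a data frame of
#'   per-stage removed and surviving variant counts in application order,
#'   carrying the removed variant rows as the `removed` attribute (a
#'   named list of data frames, one per stage).
#' @export
apply_variant_filters <- function(dataset, thresholds = filter_thresholds()) {
  th <- thresholds
  n_input <- nrow(dataset$variants)
  stages <- character(0)
  removed <- list()
  counts <- integer(0)

  run_stage <- function(name, res) {
    stages <<- c(stages, name)
    removed[[name]] <<- res$removed
    counts <<- c(counts, nrow(res$removed))
    res$dataset
  }
  vqsr_stage <- function(d) run_stage("vqsr", apply_vqsr(d))
  manual_stages <- function(d) {
    d <- run_stage("hwe", hwe_filter(d, alpha = th$hwe_alpha))
    ag <- if (nrow(d$variants) > 0) average_gq(d) else numeric(0)
    keep <- if (th$min_avg_gq <= 0) {
      rep(TRUE, nrow(d$variants))   # filter disabled
    } else {
      !is.na(ag) & ag >= th$min_avg_gq
    }
    d <- run_stage("avg_gq", list(
      dataset = d[keep, ],
      removed = local({
        r <- d$variants[!keep, , drop = FALSE]; rownames(r) <- NULL; r
      })))
    cr <- call_rate(d)
    keep <- cr >= th$min_call_rate
    run_stage("call_rate", list(
      dataset = d[keep, ],
      removed = local({
        r <- d$variants[!keep, , drop = FALSE]; rownames(r) <- NULL; r
      })))
  }

  d <- dataset
  if (th$vqsr_position == "before_manual") d <- vqsr_stage(d)
  d <- manual_stages(d)
  if (th$vqsr_position == "after_manual") d <- vqsr_stage(d)

  report <- data.frame(
    stage = stages,
    n_removed = counts,
    n_remaining = n_input - cumsum(counts)
  )
  attr(report, "removed") <- removed
  list(dataset = d, report = report)
}
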