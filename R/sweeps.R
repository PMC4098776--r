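# Threshold-derivation sweeps: recompute the filter outcome over a grid
# of thresholds and select the largest threshold still meeting a
# retention target. Every sweep point is a full single-threshold run, so
# each point can be reproduced independently.

#' Sweep a genotype-filter threshold against array concordance
#'
#' For each grid threshold, applies the single genotype filter (DP or GQ)
#' and records, relative to the unfiltered comparison: the fraction of
#' non-reference discordant genotypes removed, the fraction of
#' non-reference concordant genotypes retained, and the sensitivity and
#' specificity of the surviving comparisons.
#'
#' @param dataset A [cohort_dataset()].
#' @param array An [array_genotypes()] gold standard.
#' @param which `"dp"` or `"gq"`.
#' @param grid Ascending numeric thresholds.
#' @return A data frame of class `sweep_curve` with column `threshold`
#'   and metric columns `pct_discordant_removed`,
#'   `pct_concordant_retained`, `sensitivity`, `specificity`.
#' @export
sweep_genotype_thresholds <- function(dataset, array,
                                      which = c("dp", "gq"),
                                      grid = 0:30) {
  which <- match.arg(which)
  check_grid(grid)
  base <- concordance_report(dataset, array)
  rows <- lapply(grid, function(t) {
    f <- if (which == "dp") {
      apply_genotype_filters(dataset, min_dp = t, min_gq = 0)
    } else {
      apply_genotype_filters(dataset, min_dp = 0, min_gq = t)
    }
    tab <- concordance_report(f$dataset, array)
    rf <- removal_fractions(base, tab)
    m <- metrics_from_counts(tab)
    data.frame(
      threshold = t,
      pct_discordant_removed = rf$pct_discordant_removed,
      pct_concordant_retained = 1 - rf$pct_concordant_removed,
      sensitivity = m$sensitivity,
      specificity = m$specificity
    )
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("sweep_curve", "data.frame"),
            metric_name = which)
}

#' Sweep a variant-metric threshold against Ti/Tv and truth retention
#'
#' For each grid threshold, restricts the dataset to variants whose
#' average GQ (or call rate) meets the threshold and records the Ti/Tv
#' ratio of survivors in each stratum plus the fraction of truth-set
#' variants retained relative to the unfiltered input. Run after genotype
#' masking.
#'
#' @param dataset A [cohort_dataset()].
#' @param which `"avg_gq"` or `"call_rate"`.
#' @param grid Ascending numeric thresholds (defaults 0-90 by 1 for
#'   average GQ, 0-1 by 0.02 for call rate).
#' @param known,truth [site_set()]s.
#' @return A data frame of class `sweep_curve` with columns `threshold`,
#'   `n_variants`, `titv_all`, `titv_known`, `titv_novel`, `titv_truth`
#'   and `truth_retention`.
#' @export
sweep_variant_metric <- function(dataset, which = c("avg_gq", "call_rate"),
                                 grid = NULL, known = NULL, truth = NULL) {
  which <- match.arg(which)
  if (is.null(grid)) {
    grid <- if (which == "avg_gq") 0:90 else seq(0, 1, by = 0.02)
  }
  check_grid(grid)
  metric <- if (which == "avg_gq") average_gq(dataset) else call_rate(dataset)
  rows <- lapply(grid, function(t) {
    keep <- if (t <= 0) {
      rep(TRUE, nrow(dataset$variants))
    } else {
      !is.na(metric) & metric >= t
    }
    d <- dataset[keep, ]
    tv <- titv_summary(d, known = known, truth = truth)
    ratio <- function(s) tv$ratio[tv$stratum == s]
    data.frame(
      threshold = t,
      n_variants = nrow(d$variants),
      titv_all = ratio("all"), titv_known = ratio("known"),
      titv_novel = ratio("novel"), titv_truth = ratio("truth"),
      truth_retention = suppressMessages(
        truth_retention(dataset, d, truth))
    )
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("sweep_curve", "data.frame"),
            metric_name = which)
}

#' Select a threshold from a sweep curve by a retention target
#'
#' Returns the largest grid threshold whose retention metric is still at
#' least `min_retention` — the most stringent filter that sacrifices no
#' more than the allowed fraction (e.g. average GQ >= 35 at 99% truth
#' sensitivity; call rate >= 0.88 at 96% truth retention).
#'
#' @param curve A `sweep_curve`.
#' @param retention_metric Name of the curve column holding the retention
#'   value.
#' @param min_retention Minimum acceptable retention, a fraction.
#' @return The selected threshold.
#' @export
select_threshold <- function(curve, retention_metric, min_retention) {
  if (!retention_metric %in% names(curve)) {
    stop("curve has no metric '", retention_metric, "'", call. = FALSE)
  }
  ok <- !is.na(curve[[retention_metric]]) &
    curve[[retention_metric]] >= min_retention
  if (!any(ok)) {
    stop("no grid threshold meets retention >= ", min_retention,
         call. = FALSE)
  }
  max(curve$threshold[ok])
}

check_grid <- function(grid) {
  if (length(grid) == 0) stop("grid must be non-empty", call. = FALSE)
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid thresholds must be strictly increasing", call. = FALSE)
  }
  invisible(grid)
}
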