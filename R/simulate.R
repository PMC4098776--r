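# Synthetic cohorts with known truth.
#
# The generator emulates the statistical structure the filters assume:
# genotypes drawn under Hardy-Weinberg over a site-frequency-like MAF
# spectrum (with a designated fraction of heterozygote-excess violating
# sites), per-genotype read depth from batch-specific negative-binomial
# models (zero off the batch's capture target), GQ increasing in depth,
# genotype errors injected at exactly the Phred-implied rate 10^(-GQ/10)
# with adjacent-class bias, artifact ("false") sites whose true genotype
# is homozygous reference everywhere, VQSR failure enriched at artifact
# sites, true sites drawn at Ti/Tv ~ 2.8 and artifact sites at the
# random expectation 0.5, an array gold standard over a sample subset,
# and an imputed panel whose genotype quality falls as R-squared falls.

#' Simulation configuration
#'
#' Defaults describe a two-batch cohort of 200 samples and 20,000 sites
#' with 10% artifact sites, 5% heterozygote-excess sites and
#' batch-specific capture targets (15% of sites off-target in the second
#' batch), at mean on-target depth 30.
#'
#' @param n_samples,n_variants Cohort dimensions.
#' @param maf_shape1,maf_shape2 Beta parameters of the minor-allele
#'   frequency distribution (clamped to `[0.005, 0.5]`); the default
#'   Beta(0.5, 5) is rare-skewed like an exome site-frequency spectrum.
#' @param n_batches Number of processing batches; samples are split as
#'   evenly as possible in roster order.
#' @param batch_mean_dp Mean on-target read depth per batch (recycled).
#' @param batch_dp_size Negative-binomial size (inverse overdispersion)
#'   of the depth model.
#' @param batch_off_target_frac Fraction of sites off-target (depth 0,
#'   genotype missing) per batch (recycled).
#' @param gq_per_dp,gq_sd GQ model: GQ ~ round(gq_per_dp * DP +
#'   Normal(0, gq_sd)), clamped to `[0, 99]`.
#' @param error_adjacent_bias Probability that a homozygous genotype
#'   errs to the adjacent heterozygote rather than the opposite
#'   homozygote.
#' @param frac_hwe_violating Fraction of true sites generated with
#'   heterozygote excess.
#' @param hwe_inbreeding Inbreeding-like distortion F (negative = excess
#'   heterozygosity) at violating sites.
#' @param frac_false_sites Fraction of sites that are sequencing
#'   artifacts: true genotype homozygous reference in every sample, depth
#'   scaled down by `false_dp_scale`, so their calls arise from
#'   low-quality errors.
#' @param false_dp_scale Depth scale factor at artifact sites.
#' @param titv_true,titv_false Ti/Tv ratio at which true / artifact site
#'   substitution classes are drawn (2.8 for a high-quality exome set;
#'   0.5 is the random expectation).
#' @param known_frac_true,known_frac_false Probability of membership in
#'   the "known" (dbSNP-like) set for true / artifact sites.
#' @param truth_frac_known Probability that a known true site is also in
#'   the "truth" (HapMap-like) set.
#' @param vqsr_fail_true,vqsr_fail_false Probability of failing VQSR for
#'   true / artifact sites.
#' @param array_n_samples Number of samples on the array gold standard.
#' @param array_error_rate Per-genotype array error probability.
#' @param array_low_gencall_frac Fraction of array records drawn with a
#'   GenCall score below 0.3.
#' @param imputed_frac_low_r2 Mixture weight of the low-R-squared
#'   component of the imputed panel (destined for the no-genotype class).
#' @param imputed_gq_per_r2,imputed_gq_sd Imputed-GQ model: GQ ~
#'   round(imputed_gq_per_r2 * r2 + Normal(0, imputed_gq_sd)), clamped to
#'   `[0, 99]`.
#' @param seed Integer seed; a fixed seed fixes the output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200, n_variants = 20000,
                       maf_shape1 = 0.5, maf_shape2 = 5,
                       n_batches = 2,
                       batch_mean_dp = 30, batch_dp_size = 8,
                       batch_off_target_frac = c(0, 0.15),
                       gq_per_dp = 2.2, gq_sd = 8,
                       error_adjacent_bias = 0.9,
                       frac_hwe_violating = 0.05, hwe_inbreeding = -0.5,
                       frac_false_sites = 0.10, false_dp_scale = 0.25,
                       titv_true = 2.8, titv_false = 0.5,
                       known_frac_true = 0.6, known_frac_false = 0.1,
                       truth_frac_known = 0.35,
                       vqsr_fail_true = 0.05, vqsr_fail_false = 0.8,
                       array_n_samples = 10, array_error_rate = 0.001,
                       array_low_gencall_frac = 0.05,
                       imputed_frac_low_r2 = 0.45,
                       imputed_gq_per_r2 = 60, imputed_gq_sd = 10,
                       seed = 1L) {
  cfg <- as.list(environment())
  fracs <- c(cfg$batch_off_target_frac, cfg$frac_hwe_violating,
             cfg$frac_false_sites, cfg$known_frac_true,
             cfg$known_frac_false, cfg$truth_frac_known,
             cfg$vqsr_fail_true, cfg$vqsr_fail_false,
             cfg$array_error_rate, cfg$array_low_gencall_frac,
             cfg$imputed_frac_low_r2, cfg$error_adjacent_bias)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all fractions must be in [0, 1]", call. = FALSE)
  }
  if (cfg$n_samples < 1 || cfg$n_variants < 1 || cfg$n_batches < 1) {
    stop("n_samples, n_variants and n_batches must be >= 1", call. = FALSE)
  }
  if (cfg$array_n_samples > cfg$n_samples) {
    stop("array_n_samples cannot exceed n_samples", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Draw ref/alt pairs at a target Ti/Tv ratio. Transitions have 4 ordered
# classes and transversions 8, so P(transition) = r / (r + 1) per site.
draw_substitutions <- function(n, titv_ratio) {
  transitions <- matrix(c("A", "G", "G", "A", "C", "T", "T", "C"),
                        ncol = 2, byrow = TRUE)
  purines <- c("A", "G"); pyrimidines <- c("C", "T")
  tvs <- rbind(
    as.matrix(expand.grid(purines, pyrimidines, stringsAsFactors = FALSE)),
    as.matrix(expand.grid(pyrimidines, purines, stringsAsFactors = FALSE)))
  is_ti <- stats::runif(n) < titv_ratio / (titv_ratio + 1)
  ti_idx <- sample.int(4, n, replace = TRUE)
  tv_idx <- sample.int(8, n, replace = TRUE)
  ref <- ifelse(is_ti, transitions[ti_idx, 1], tvs[tv_idx, 1])
  alt <- ifelse(is_ti, transitions[ti_idx, 2], tvs[tv_idx, 2])
  cbind(ref = ref, alt = alt)
}

#' Simulate a sequenced cohort with known truth
#'
#' Generates a [cohort_dataset()] plus a truth bundle carrying the true
#' genotype matrix, per-genotype error flags and per-variant labels
#' (artifact site, Hardy-Weinberg violating, known/truth membership,
#' per-batch on-target status). Fixed seed implies identical output.
#'
#' @param config A [sim_config()].
#' @return List with elements `dataset` (a `cohort_dataset` with batch
#'   assignment), `truth` (list: `gt_true` matrix, `error` logical
#'   matrix, `labels` per-variant data frame, `on_target` variants x
#'   batches logical matrix, `batch` the sample-to-batch map, `known`
#'   and `truth_set` [site_set()]s).
#' @export
simulate_cohort <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_samples; m <- cfg$n_variants
  samples <- sprintf("S%03d", seq_len(n))
  # even contiguous split in roster order
  batch_lab <- paste0("B", sort(rep_len(seq_len(cfg$n_batches), n)))
  batch <- stats::setNames(batch_lab, samples)
  batches <- unique(batch_lab)

  is_false <- stats::runif(m) < cfg$frac_false_sites
  sub_true <- draw_substitutions(m, cfg$titv_true)
  sub_false <- draw_substitutions(m, cfg$titv_false)
  ref <- ifelse(is_false, sub_false[, "ref"], sub_true[, "ref"])
  alt <- ifelse(is_false, sub_false[, "alt"], sub_true[, "alt"])
  variants <- data.frame(
    chrom = "1", pos = seq_len(m) * 10L, ref = ref, alt = alt,
    vqsr_pass = NA
  )

  maf <- pmin(0.5, pmax(0.005, stats::rbeta(m, cfg$maf_shape1,
                                            cfg$maf_shape2)))
  hwe_viol <- !is_false & stats::runif(m) < cfg$frac_hwe_violating

  # True genotypes: HWE at conformant sites; heterozygote excess
  # P(het) = 2pq(1-F) at violating sites; artifact sites all hom-ref.
  p <- 1 - maf; q <- maf
  f <- ifelse(hwe_viol, cfg$hwe_inbreeding, 0)
  p_het <- pmin(1, pmax(0, 2 * p * q * (1 - f)))
  p_homalt <- pmax(0, q^2 + f * p * q)
  p_homref <- pmax(0, 1 - p_het - p_homalt)
  tot <- p_homref + p_het + p_homalt
  u <- matrix(stats::runif(m * n), m, n)
  gt_true <- matrix(0L, m, n)
  gt_true[u > p_homref / tot] <- 1L
  gt_true[u > (p_homref + p_het) / tot] <- 2L
  gt_true[is_false, ] <- 0L

  # Depth: per-batch negative binomial, scaled down at artifact sites,
  # zero off-target.
  mean_dp <- rep_len(cfg$batch_mean_dp, cfg$n_batches)
  off_frac <- rep_len(cfg$batch_off_target_frac, cfg$n_batches)
  on_target <- matrix(TRUE, m, cfg$n_batches,
                      dimnames = list(NULL, batches))
  dp <- matrix(0L, m, n)
  for (b in seq_along(batches)) {
    cols <- which(batch_lab == batches[b])
    on_target[, b] <- stats::runif(m) >= off_frac[b]
    mu <- ifelse(is_false, mean_dp[b] * cfg$false_dp_scale, mean_dp[b])
    d <- matrix(
      stats::rnbinom(m * length(cols), size = cfg$batch_dp_size,
                     mu = rep(mu, length(cols))),
      m, length(cols))
    d[!on_target[, b], ] <- 0L
    dp[, cols] <- d
  }

  gq <- matrix(
    pmax(0L, pmin(99L, as.integer(round(
      cfg$gq_per_dp * dp + stats::rnorm(m * n, 0, cfg$gq_sd))))),
    m, n)

  # Calls: missing where depth is zero; otherwise the true genotype,
  # corrupted with probability 10^(-GQ/10) toward an adjacent class.
  err <- matrix(stats::runif(m * n) < 10^(-gq / 10), m, n)
  err[dp == 0L] <- FALSE
  gt_obs <- gt_true
  adjacent <- matrix(stats::runif(m * n) < cfg$error_adjacent_bias, m, n)
  het_up <- matrix(stats::runif(m * n) < 0.5, m, n)
  e <- which(err)
  g <- gt_true[e]
  new_g <- integer(length(e))
  new_g[g == 0L] <- ifelse(adjacent[e][g == 0L], 1L, 2L)
  new_g[g == 2L] <- ifelse(adjacent[e][g == 2L], 1L, 0L)
  new_g[g == 1L] <- ifelse(het_up[e][g == 1L], 2L, 0L)
  gt_obs[e] <- new_g
  gt_obs[dp == 0L] <- NA_integer_
  gq[dp == 0L] <- NA_integer_
  dp_na <- dp
  dp_na[dp == 0L] <- NA_integer_

  variants$vqsr_pass <- ifelse(
    is_false,
    stats::runif(m) >= cfg$vqsr_fail_false,
    stats::runif(m) >= cfg$vqsr_fail_true)

  known <- !is_false & stats::runif(m) < cfg$known_frac_true
  known[is_false] <- stats::runif(sum(is_false)) < cfg$known_frac_false
  truth_mem <- known & !is_false & stats::runif(m) < cfg$truth_frac_known

  dataset <- cohort_dataset(samples, variants, gt = gt_obs, dp = dp_na,
                            gq = gq, batch = batch)
  labels <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt,
    false_site = is_false, hwe_violating = hwe_viol,
    known_member = known, truth_member = truth_mem, maf = maf
  )
  truth <- list(
    gt_true = gt_true, error = err & dp > 0L, labels = labels,
    on_target = on_target, batch = batch,
    known = site_set(labels[labels$known_member, , drop = FALSE]),
    truth_set = site_set(labels[labels$truth_member, , drop = FALSE]),
    samples = samples
  )
  list(dataset = dataset, truth = truth)
}

#' Simulate array gold-standard genotypes from a truth bundle
#'
#' Emits array genotypes equal to the true genotypes on a sample subset,
#' corrupted at `array_error_rate`, with GenCall scores drawn so that a
#' configurable fraction falls below the 0.3 confidence cutoff.
#'
#' @param truth The `truth` element of [simulate_cohort()]'s result.
#' @param sample_subset Samples assayed on the array (default: the first
#'   `array_n_samples` of the roster).
#' @param array_error_rate Per-genotype corruption probability.
#' @param low_gencall_frac Fraction of records with GenCall score below
#'   0.3.
#' @param seed Integer seed.
#' @return An [array_genotypes()] object (all records, including those
#'   below GenCall 0.3 — apply the cutoff via [read_array_genotypes()]
#'   semantics or subset on `gencall_score`).
#' @export
simulate_array <- function(truth, sample_subset = NULL,
                           array_error_rate = 0.001,
                           low_gencall_frac = 0.05, seed = 1L) {
  set.seed(seed)
  if (is.null(sample_subset)) {
    sample_subset <- utils::head(truth$samples, 10)
  }
  if (!all(sample_subset %in% truth$samples)) {
    stop("unknown sample(s) in array subset", call. = FALSE)
  }
  if (length(sample_subset) == 0) {
    return(array_genotypes(data.frame(
      sample = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(), genotype = integer(),
      gencall_score = numeric())))
  }
  cols <- match(sample_subset, truth$samples)
  lab <- truth$labels
  m <- nrow(lab); k <- length(cols)
  g <- truth$gt_true[, cols, drop = FALSE]
  err <- matrix(stats::runif(m * k) < array_error_rate, m, k)
  shift <- matrix(sample(c(1L, 2L), m * k, replace = TRUE), m, k)
  g[err] <- (g[err] + shift[err]) %% 3L
  score <- ifelse(stats::runif(m * k) < low_gencall_frac,
                  stats::runif(m * k, 0, 0.3),
                  stats::runif(m * k, 0.3, 1))
  array_genotypes(data.frame(
    sample = rep(sample_subset, each = m),
    chrom = rep(lab$chrom, k), pos = rep(lab$pos, k),
    ref = rep(lab$ref, k), alt = rep(lab$alt, k),
    genotype = as.integer(g),
    gencall_score = as.numeric(score)
  ))
}

#' Simulate an imputed genotype panel with known truth
#'
#' Per-variant R-squared is drawn from a two-component mixture (a low
#' component destined for the no-genotype class, mean ~0.06, and a high
#' component, mean ~0.83); per-genotype GQ increases with R-squared and
#' genotypes are corrupted with probability 10^(-GQ/10), so genotype
#' errors are GQ-driven.
#'
#' @param config A [sim_config()] (`n_samples`, `n_variants`,
#'   `imputed_*`, `maf_*` and Ti/Tv parameters are used).
#' @return List with `panel` (an [imputed_panel()]) and `truth` (list
#'   with `gt_true`, `error`, `r2`).
#' @export
simulate_imputed <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  n <- cfg$n_samples; m <- cfg$n_variants
  samples <- sprintf("S%03d", seq_len(n))
  sub <- draw_substitutions(m, cfg$titv_true)
  low <- stats::runif(m) < cfg$imputed_frac_low_r2
  r2 <- ifelse(low, stats::rbeta(m, 0.6, 9), stats::rbeta(m, 8, 1.6))

  maf <- pmin(0.5, pmax(0.001, stats::rbeta(m, cfg$maf_shape1,
                                            cfg$maf_shape2)))
  gt_true <- matrix(
    stats::rbinom(m * n, 1, rep(maf, n)) +
      stats::rbinom(m * n, 1, rep(maf, n)),
    m, n)
  gq <- matrix(
    pmax(0L, pmin(99L, as.integer(round(
      cfg$imputed_gq_per_r2 * r2 +
        stats::rnorm(m * n, 0, cfg$imputed_gq_sd))))),
    m, n)
  err <- matrix(stats::runif(m * n) < 10^(-gq / 10), m, n)
  gt_obs <- gt_true
  adjacent <- matrix(stats::runif(m * n) < cfg$error_adjacent_bias, m, n)
  het_up <- matrix(stats::runif(m * n) < 0.5, m, n)
  e <- which(err)
  g <- gt_true[e]
  new_g <- integer(length(e))
  new_g[g == 0L] <- ifelse(adjacent[e][g == 0L], 1L, 2L)
  new_g[g == 2L] <- ifelse(adjacent[e][g == 2L], 1L, 0L)
  new_g[g == 1L] <- ifelse(het_up[e][g == 1L], 2L, 0L)
  gt_obs[e] <- new_g

  variants <- data.frame(
    chrom = "2", pos = seq_len(m) * 10L, ref = sub[, "ref"],
    alt = sub[, "alt"], vqsr_pass = TRUE, r2 = r2)
  panel <- imputed_panel(samples, variants, gt = gt_obs, gq = gq)
  list(panel = panel,
       truth = list(gt_true = gt_true, error = err, r2 = r2))
}
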