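---
title: "Genotype and variant filtering for exome cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype and variant filtering for exome cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoqc)
```

## The problem

Multi-sample exome callsets produced by standard best-practice pipelines
carry two distinct kinds of error. *Variant-level* artifacts — spurious
sites created by mismapping or systematic sequencing error — are
partially handled upstream by VQSR, whose pass/fail verdict arrives in
the VCF FILTER column. *Genotype-level* errors — wrong calls at real
sites, concentrated where read depth or genotype quality is low — are
not addressed by VQSR at all. Both depress the power of downstream
association tests; heterozygote↔homozygote errors at rare variants are
the most damaging, because rare-variant collapsing tests aggregate
exactly those genotypes.

`exoqc` implements a two-level filtering cascade with the evaluation
tooling required to defend each threshold: genotype masking by DP and
GQ, then variant removal by Hardy-Weinberg disequilibrium, average GQ,
call rate and the VQSR verdict, run per processing batch and merged.

## Genotype filters and their probabilistic rationale

A called genotype is masked — set to missing, never deleted — when its
depth or quality falls below threshold.

* **DP ≥ 8.** Under a two-tailed binomial model in which each of a
  heterozygote's alleles is equally likely to be drawn in each read, all
  `DP` reads show the same allele with probability `2·(1/2)^DP`
  (`het_mono_probability()`). Eight reads bring this below 1%
  (0.78%); eleven reads would be needed for 0.1%.
* **GQ ≥ 20.** A Phred-scaled genotype quality `GQ` corresponds to call
  accuracy `1 − 10^(−GQ/10)` (`phred_accuracy()`): 99% at 20, 99.9% at
  30. The 99% criterion matches the depth threshold's confidence level.

Because both rationales are probabilistic statements about the genotype
itself, independent of any particular dataset, these two defaults are
portable across studies. Masking rather than deleting is load-bearing:
the call-rate filter later counts masked genotypes as missing, which is
how genotype-level quality propagates into variant-level filtering. A
called genotype whose DP or GQ field is absent fails any positive
threshold (conservative); a threshold of zero disables the
corresponding filter entirely, including for absent fields, so that the
zero-threshold cascade is the identity.

Homozygous-reference genotypes are filtered under the same thresholds as
non-reference ones: reference-call accuracy matters for rare-variant
tests, and the reporting splits all removals into reference and
non-reference classes.

## The Hardy-Weinberg exact test

The HWE filter uses the exact conditional distribution of the
heterozygote count given the minor-allele count and sample size
(Levene–Haldane): the p-value sums the probabilities of all achievable
heterozygote counts no more probable than the observed one — a plain
exact tail, no mid-p adjustment, matching the behaviour of the exact
test in standard variant-filtering tools. The chi-square approximation
was rejected deliberately: it is anti-conservative at rare minor-allele
frequencies, which is exactly where an exome cohort's variants
concentrate.

Implementation notes:

* probabilities are built by a two-sided recurrence from the modal
  heterozygote count and normalised at the end, which is numerically
  stable out to cohort sizes far beyond this package's needs; the test
  suite checks agreement with a direct log-factorial enumeration oracle
  to 10⁻¹² over every configuration of up to 50 diploids;
* "no more probable than observed" is evaluated with a relative slack of
  10⁻⁷ so that exact probability ties (which occur for symmetric
  configurations) are classified stably under floating point;
* a monomorphic site has a single achievable configuration and p = 1;
  sites with no genotypes left after masking are not testable and are
  not counted in the correction.

The Bonferroni correction divides `α = 0.05` by the number of testable
variants *in the dataset being filtered* — per batch when filtering is
batched. The scope of the correction was a genuinely open choice; the
per-dataset scope was chosen because it makes each batch's test
self-contained and reproducible from that batch alone. Boundary
p-values exactly equal to the corrected threshold are removed ("p ≤ α"
read literally). All samples enter the test; the package does not model
relatedness (the intended cohorts are population-based).

## Variant filters, order, and batching

After masking, the cascade applies HWE, then average GQ (mean of GQ over
non-missing genotypes; a variant left with no genotypes fails any
positive threshold), then call rate (non-missing fraction over the full
batch roster), then the VQSR verdict. Thresholds are "keep if ≥"; the
defaults (average GQ ≥ 35, call rate ≥ 0.88) are the
retention-target-derived values — see the sweep machinery below — and
unlike the genotype thresholds they are dataset-derived quantities that
users should re-derive for their own cohorts.

Placing the VQSR verdict *after* the manual filters is the default
because it consistently yields a higher survivor Ti/Tv: the manual
filters remove some variants that VQSR would have passed, and the
transversion-enriched overlap is removed either way, so the order
matters only through the variants each stage spares.
`compare_filter_orders()` quantifies the difference and tests
transversion enrichment of the extra removals with a one-tailed
hypergeometric test (`tv_enrichment_pvalue()`). One tail — excess
transversion removal — is the direction a quality-improving filter
should show; the test conditions on the pre-filter pool of the stage
being tested.

Batching: `run_batched_pipeline()` splits samples by their processing
batch (capture kit, chemistry), runs the full cascade per batch and
merges the union of per-batch survivors. For a merged variant, genotypes
come from the batches where it passed; samples from batches where it
failed or was off-target are set missing, and that masking is recorded
in the merge's `passed_in` map rather than silently mixed into the
genotype matrix. This policy (rather than, say, carrying the failing
batch's genotypes through) was chosen so that every genotype in the
merged output has survived the cascade in its own batch.

## Concordance evaluation

Array genotypes (GenCall score ≥ 0.30) are the gold standard.
Classification is by alternate-allele dosage: identical
homozygous-reference pairs are TN, identical het/hom-alt pairs TP, a
sequencing call missing at least one alternate allele relative to the
array is FN, one with at least one extra alternate allele FP. This
makes the four classes exhaustive over the nine called genotype pairs,
and sensitivity `TP/(TP+FN)` coincides with non-reference concordance.
Missing sequencing genotypes are *excluded* from comparison rather than
counted as FN — that is what makes "percent of discordant genotypes
removed" a meaningful measure of a genotype filter. Comparisons require
an exact (chrom, pos, ref, alt) key match; allele harmonization and
strand flipping are upstream concerns and are not attempted.

## Threshold sweeps

`sweep_genotype_thresholds()` and `sweep_variant_metric()` recompute the
full single-threshold outcome at every grid point (no incremental
shortcuts — each point is independently reproducible, and the test suite
asserts exactly that). `select_threshold()` formalises threshold choice
as "the largest grid threshold whose retention metric still meets the
target", e.g. a 99% truth-variant sensitivity target for average GQ and
96% for call rate. Default grids are DP 0–30 and GQ 0–60 by 1, average
GQ 0–90 by 1, call rate 0–1 by 0.02 — wide enough to contain the
plateaus those metrics show in practice, and configurable.

## Imputed panels

Imputed genotypes carry a GQ derived from the imputation engine's
genotype probabilities and a per-variant allelic R². The same GQ ≥ 20
masking applies; variants left monoallelic (all surviving genotypes the
same homozygote — hom-ref-only and hom-alt-only are treated alike) or
with no genotypes at all are pruned as uninformative. The conventional
hard `R² > 0.3` cutoff (strict inequality) is implemented as a
comparison baseline; when genotype errors are driven by per-genotype
confidence, GQ masking removes a larger fraction of truth-discordant
genotypes than the R² cutoff, because the cutoff can only act on whole
variants.

## The synthetic-data generator

`simulate_cohort()` generates the study conditions every test runs
under. Defaults, chosen once as a realistic two-batch exome cohort and
not revisited:

* 200 samples × 20,000 biallelic SNVs, two equal batches;
* minor-allele frequencies from Beta(0.5, 5) clamped to [0.005, 0.5] — a
  rare-skewed spectrum;
* true genotypes drawn under HWE, except a 5% fraction of sites
  generated with heterozygote excess (inbreeding-like distortion
  F = −0.5), the signature the HWE filter targets;
* 10% artifact sites whose true genotype is homozygous reference in
  every sample, sequenced at a quarter of the usual depth, so their
  non-reference calls arise from low-quality errors; substitution
  classes are drawn at Ti/Tv 2.8 for true sites and 0.5 (the random
  expectation) for artifacts, giving Ti/Tv-based checks their signal;
* read depth per genotype from a negative binomial (mean 30, size 8 on
  target; zero off target — the second batch leaves 15% of sites
  off-target, creating the call-rate heterogeneity that batching is
  meant to absorb);
* GQ ≈ 2.2·DP + Normal(0, 8), clamped to [0, 99], so quality rises with
  depth;
* each called genotype is corrupted with probability exactly
  `10^(−GQ/10)`, biased toward the adjacent genotype class (hom↔het
  flips more likely than hom-ref↔hom-alt), making the Phred calibration
  of the error model literal: among genotypes with GQ = 20 the realised
  error rate is 1% up to binomial noise, which the tests verify;
* VQSR failure probability 0.8 at artifact sites and 0.05 at true
  sites; known-set membership 60%/10% (true/artifact), with 35% of known
  true sites also in the truth set — proportions in the range reported
  for real exome cohorts;
* the array gold standard covers 10 samples with configurable error
  rate and a 5% tail of sub-0.3 GenCall scores; the imputed panel draws
  R² from a low/high mixture (means ≈ 0.06 and 0.83) with GQ increasing
  in R².

What the generator does *not* emulate: linkage disequilibrium, allele-
frequency-dependent caller behaviour, strand or context-specific error
(no CpG effects), relatedness, and indels. Passing the parameter-
recovery tests therefore shows that the cascade removes the error
structure it models — calibrated genotype errors, artifact sites,
batch-target heterogeneity — not that it is optimal on any particular
real cohort.

## Numerical and degenerate-input choices

* Genotypes are unphased and unordered; half-missing calls ("0/.") are
  coerced to fully missing with a logged count (the data model forbids
  them — a genotype is missing as a unit).
* FILTER "." is treated as passing, so pre-VQSR VCFs are accepted.
* Multiallelic records are split into one biallelic variant per SNV
  alternate by default (dosage of that alternate), since every metric is
  defined per biallelic SNV; splitting can be disabled, in which case
  such records are skipped with a count.
* Ti/Tv ratios are undefined (NA) when the transversion count is zero;
  truth retention over an empty truth baseline is reported as 1 with a
  message.
* The hypergeometric null-calibration property is asserted as
  sub-uniformity (`P(p ≤ a) ≤ a` at several levels) rather than a
  goodness-of-fit test against the continuous uniform, because exact
  p-values on a discrete support are super-uniform by construction.

## Problem sizes used by the test suite

The package's own checks run the full cascade on a 200 × 20,000 cohort
(the generator's default study conditions), exhaustive oracle
enumeration up to 50 diploids for the HWE test and pools of 30 for the
hypergeometric test, and smaller seeded cohorts (60 × 3,000 and below)
for per-module properties and sweep-point reproducibility.

## Known limitations

* The HWE test assumes unrelated samples; founder selection is out of
  scope.
* No allele harmonization against array strand/orientation: inputs must
  already be in genome orientation.
* Indels and structural variants are out of scope by design; VQSR
  retraining and the imputation computation itself are consumed, never
  recomputed.
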