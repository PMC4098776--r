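Package: exoqc
Title: Quality-Control Filtering for Population-Scale Exome Sequencing Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotype- and variant-level quality-control filters for
    multi-sample whole-exome sequencing (WES) callsets, applied in a
    prescribed order and per processing batch. Implements depth (DP) and
    genotype-quality (GQ) masking with their probabilistic rationale, a
    Hardy-Weinberg exact test with Bonferroni correction, average-GQ and
    call-rate variant filters, application of an upstream VQSR verdict,
    transition/transversion (Ti/Tv) accounting stratified by known/novel/
    truth site sets, sequencing-versus-array genotype concordance with
    sensitivity and specificity, hypergeometric transversion-enrichment
    tests, threshold-derivation sweeps, batch-aware filtering with merge
    of per-batch survivors, and filters for imputed genotype panels
    (GQ masking, monoallelic/no-genotype pruning, and an allelic R-squared
    cutoff baseline). A synthetic-cohort simulator with known truth
    genotypes makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
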