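# Core data model: a cohort of diploid samples genotyped at biallelic SNVs.
#
# Genotypes are stored as an integer dosage matrix (variants x samples):
# 0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternate,
# NA = missing. Genotypes are unphased and unordered. Per-genotype read
# depth (DP) and Phred-scaled genotype quality (GQ) live in parallel
# integer matrices, NA where the field is absent.

#' Construct a cohort dataset
#'
#' Bundles the sample roster, the ordered variant table and the genotype,
#' depth and quality matrices of a multi-sample SNV callset into a single
#' validated object. This is the container every filter in the package
#' consumes and returns.
#'
#' @param samples Character vector of unique sample identifiers; defines
#'   the column order of the matrices.
#' @param variants Data frame with columns `chrom` (character), `pos`
#'   (1-based integer position, VCF convention), `ref` and `alt` (single
#'   nucleotides in A/C/G/T), and `vqsr_pass` (logical verdict consumed
#'   from the VCF FILTER column). Variant identity is the full
#'   (chrom, pos, ref, alt) key, which must be unique.
#' @param gt Integer matrix of alternate-allele dosages, one row per
#'   variant and one column per sample; values 0, 1, 2 or NA (missing).
#' @param dp,gq Integer matrices of per-genotype read depth and genotype
#'   quality, same shape as `gt`; NA where the field is absent.
#' @param batch Optional named character vector mapping every sample to a
#'   batch label, or NULL when no batch structure is known.
#'
#' @return An object of class `cohort_dataset`.
#' @export
cohort_dataset <- function(samples, variants, gt, dp = NULL, gq = NULL,
                           batch = NULL) {
  samples <- as.character(samples)
  n_var <- nrow(variants)
  n_smp <- length(samples)
  shape <- function(m) {
    if (is.null(m)) {
      m <- matrix(NA_integer_, n_var, n_smp)
    }
    m <- matrix(as.integer(m), n_var, n_smp)
    dimnames(m) <- list(NULL, samples)
    m
  }
  x <- structure(
    list(
      samples  = samples,
      variants = as.data.frame(variants)[, c("chrom", "pos", "ref", "alt",
                                             "vqsr_pass")],
      gt = shape(gt),
      dp = shape(dp),
      gq = shape(gq),
      batch = batch
    ),
    class = "cohort_dataset"
  )
  x$variants$chrom <- as.character(x$variants$chrom)
  x$variants$pos <- as.integer(x$variants$pos)
  x$variants$ref <- as.character(x$variants$ref)
  x$variants$alt <- as.character(x$variants$alt)
  x$variants$vqsr_pass <- as.logical(x$variants$vqsr_pass)
  rownames(x$variants) <- NULL
  validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  v <- x$variants
  if (anyDuplicated(x$samples)) {
    stop("sample identifiers must be unique", call. = FALSE)
  }
  if (nrow(v) > 0) {
    nt <- c("A", "C", "G", "T")
    if (!all(v$ref %in% nt) || !all(v$alt %in% nt)) {
      stop("ref and alt must be single nucleotides (A/C/G/T)", call. = FALSE)
    }
    if (any(v$ref == v$alt)) {
      stop("ref and alt must differ (biallelic SNV)", call. = FALSE)
    }
    if (any(v$pos < 1L)) {
      stop("positions are 1-based and must be >= 1", call. = FALSE)
    }
    if (anyDuplicated(variant_keys(x))) {
      stop("variant keys (chrom, pos, ref, alt) must be unique",
           call. = FALSE)
    }
  }
  for (f in c("gt", "dp", "gq")) {
    if (!identical(dim(x[[f]]), c(nrow(v), length(x$samples)))) {
      stop(sprintf("'%s' matrix must be n_variants x n_samples", f),
           call. = FALSE)
    }
  }
  bad <- x$gt[!is.na(x$gt)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype dosages must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (any(x$dp < 0L, na.rm = TRUE) || any(x$gq < 0L, na.rm = TRUE)) {
    stop("DP and GQ must be non-negative", call. = FALSE)
  }
  if (!is.null(x$batch)) {
    if (!all(x$samples %in% names(x$batch))) {
      stop("batch assignment must cover every sample", call. = FALSE)
    }
  }
  invisible(x)
}

#' Variant identity keys
#'
#' @param x A `cohort_dataset`, an imputed panel, or a data frame with
#'   chrom/pos/ref/alt columns.
#' @return Character vector of `chrom:pos:ref:alt` keys.
#' @export
variant_keys <- function(x) {
  v <- if (is.data.frame(x)) x else x$variants
  paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
}

#' @export
#' @method print cohort_dataset
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d samples x %d variants\n",
              length(x$samples), nrow(x$variants)))
  if (!is.null(x$batch)) {
    cat("  batches:", paste(sort(unique(x$batch)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a cohort dataset
#'
#' @param x A `cohort_dataset`.
#' @param i Variant (row) index, logical or integer.
#' @param j Sample (column) index, logical, integer or sample names.
#' @param ... Unused.
#' @return A `cohort_dataset` restricted to the selected variants/samples.
#' @export
`[.cohort_dataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$variants))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(j)) j <- match(j, x$samples)
  out <- x
  out$variants <- x$variants[i, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$gt <- x$gt[i, j, drop = FALSE]
  out$dp <- x$dp[i, j, drop = FALSE]
  out$gq <- x$gq[i, j, drop = FALSE]
  out$samples <- x$samples[j]
  if (!is.null(x$batch)) out$batch <- x$batch[out$samples]
  out
}

#' Per-variant genotype counts
#'
#' Counts homozygous-reference, heterozygous and homozygous-alternate
#' genotypes per variant over the non-missing genotypes — the input to the
#' Hardy-Weinberg exact test.
#'
#' @param dataset A `cohort_dataset`.
#' @return Integer matrix with columns `n_hom_ref`, `n_het`, `n_hom_alt`.
#' @export
genotype_counts <- function(dataset) {
  gt <- dataset$gt
  cbind(
    n_hom_ref = rowSums(gt == 0L, na.rm = TRUE),
    n_het     = rowSums(gt == 1L, na.rm = TRUE),
    n_hom_alt = rowSums(gt == 2L, na.rm = TRUE)
  )
}

#' Construct a site set
#'
#' A site set carries membership of (chrom, pos, ref, alt) keys, used for
#' the "known" (dbSNP-style) and "truth" (HapMap-style) strata of Ti/Tv
#' summaries and for truth-retention computations.
#'
#' @param chrom,pos,ref,alt Vectors defining the member sites, or a single
#'   data frame passed as `chrom` with those columns.
#' @return An object of class `site_set` (data frame of unique keys).
#' @export
site_set <- function(chrom, pos = NULL, ref = NULL, alt = NULL) {
  df <- if (is.data.frame(chrom)) {
    chrom[, c("chrom", "pos", "ref", "alt")]
  } else {
    data.frame(chrom = as.character(chrom), pos = as.integer(pos),
               ref = as.character(ref), alt = as.character(alt))
  }
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  if (nrow(df) && any(df$pos < 1L)) {
    stop("site positions are 1-based and must be >= 1", call. = FALSE)
  }
  df <- unique(df)
  rownames(df) <- NULL
  structure(df, class = c("site_set", "data.frame"))
}

#' Site-set membership of a cohort's variants
#'
#' @param x A `cohort_dataset` or variant data frame.
#' @param set A `site_set` (NULL means an empty set).
#' @return Logical vector, one entry per variant.
#' @export
in_site_set <- function(x, set) {
  if (is.null(set) || nrow(set) == 0) {
    return(rep(FALSE, length(variant_keys(x))))
  }
  variant_keys(x) %in% variant_keys(set)
}

#' Construct an array genotype gold standard
#'
#' Array genotypes are the "gold standard" for concordance evaluation: one
#' genotype per (sample, site) with its GenCall confidence score. Records
#' below the configured minimum GenCall score are excluded at read time.
#'
#' @param df Data frame with columns `sample`, `chrom`, `pos`, `ref`,
#'   `alt`, `genotype` (one of `HOM_REF`, `HET`, `HOM_ALT`) and
#'   `gencall_score` in `[0, 1]`.
#' @return An object of class `array_genotypes`; `genotype` is recoded to
#'   an integer alternate-allele dosage 0/1/2.
#' @export
array_genotypes <- function(df) {
  need <- c("sample", "chrom", "pos", "ref", "alt", "genotype",
            "gencall_score")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("array table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[, need]
  if (is.character(df$genotype) || is.factor(df$genotype)) {
    code <- c(HOM_REF = 0L, HET = 1L, HOM_ALT = 2L)
    tok <- as.character(df$genotype)
    if (!all(tok %in% names(code))) {
      stop("unknown genotype token: ",
           paste(unique(setdiff(tok, names(code))), collapse = ", "),
           call. = FALSE)
    }
    df$genotype <- unname(code[tok])
  }
  df$genotype <- as.integer(df$genotype)
  if (any(is.na(df$genotype)) || any(df$genotype < 0L | df$genotype > 2L)) {
    stop("array genotypes must be HOM_REF/HET/HOM_ALT", call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  key <- paste(df$sample, df$chrom, df$pos, df$ref, df$alt, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, site) records in array table", call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("array_genotypes", "data.frame"))
}
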