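# TSV readers for the array gold standard, site-membership lists and
# sample-to-batch assignments. All accept gzip-compressed input (R file
# connections decompress transparently).

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read array gold-standard genotypes
#'
#' Reads the tab-separated array genotype table (columns `sample`,
#' `chrom`, `pos`, `ref`, `alt`, `genotype`, `gencall_score`) and drops
#' records below the GenCall confidence cutoff, mirroring the array
#' processing convention of excluding calls with GenCall score < 0.30.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @param min_gencall Minimum GenCall score; records with
#'   `gencall_score < min_gencall` are dropped.
#' @return An [array_genotypes()] object; the number of dropped records is
#'   reported via a message.
#' @export
read_array_genotypes <- function(path, min_gencall = 0.3) {
  df <- read_tsv_checked(path, c("sample", "chrom", "pos", "ref", "alt",
                                 "genotype", "gencall_score"))
  keep <- df$gencall_score >= min_gencall
  if (any(!keep)) {
    message(sum(!keep), " array record(s) below GenCall ", min_gencall,
            " dropped")
  }
  array_genotypes(df[keep, , drop = FALSE])
}

#' Read a site-membership list
#'
#' Reads a tab-separated list of (chrom, pos, ref, alt) keys — the carrier
#' for "known" (dbSNP-style) and "truth" (HapMap-style) membership.
#' Duplicate rows collapse to one key.
#'
#' @param path Path to the TSV (optionally gzipped).
#' @return A [site_set()].
#' @export
read_site_set <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "pos", "ref", "alt"))
  pos <- suppressWarnings(as.integer(df$pos))
  if (nrow(df) && any(is.na(pos))) {
    stop(basename(path), ": malformed position value", call. = FALSE)
  }
  df$pos <- pos
  site_set(df)
}

#' Read a sample-to-batch table
#'
#' @param path Path to a TSV with columns `sample` and `batch`.
#' @return Named character vector mapping sample to batch label.
#' @export
read_batch_table <- function(path) {
  df <- read_tsv_checked(path, c("sample", "batch"))
  if (anyDuplicated(df$sample)) {
    stop("sample(s) assigned to more than one batch: ",
         paste(unique(df$sample[duplicated(df$sample)]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(as.character(df$batch), as.character(df$sample))
}

#' Split a cohort by processing batch
#'
#' Restricts the cohort to each batch's sample columns, one dataset per
#' batch label. Batch-aware filtering applies the full cascade to each of
#' these independently before merging survivors.
#'
#' @param dataset A [cohort_dataset()].
#' @param batch Named character vector mapping every cohort sample to a
#'   batch label (see [read_batch_table()]), or a path to such a table.
#' @return Named list of `cohort_dataset`, one per batch label; the batch
#'   sample sets partition the cohort.
#' @export
assign_batches <- function(dataset, batch) {
  if (is.character(batch) && is.null(names(batch)) && length(batch) == 1) {
    batch <- read_batch_table(batch)
  }
  missing_s <- setdiff(dataset$samples, names(batch))
  if (length(missing_s)) {
    stop("sample(s) missing from batch table: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(batch), dataset$samples)
  if (length(unknown)) {
    stop("batch table lists unknown sample(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  labels <- unique(unname(batch[dataset$samples]))
  out <- lapply(labels, function(b) {
    keep <- dataset$samples[batch[dataset$samples] == b]
    d <- dataset[, keep]
    d$batch <- batch[keep]
    d
  })
  stats::setNames(out, labels)
}
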