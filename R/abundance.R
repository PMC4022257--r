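#' Relative abundance with a minimum-count floor
#'
#' Converts an OTU count table to relative abundances x_us = N_us / N_s,
#' where N_s is the total number of reads in sample s, then zeroes any entry
#' whose raw count is below `min_count`. The floor (default 5 reads)
#' suppresses spurious low-count detections caused by uneven sequencing
#' effort.
#'
#' @param counts Count tibble (`variable`, `var_type`, one integer column
#'   per sample), e.g. `otu_count_table()$counts`.
#' @param totals Named per-sample totals N_s. Defaults to the column sums of
#'   `counts`; pass the full per-sample read totals when the table omits
#'   unclustered reads.
#' @param min_count Counts below this are set to zero (default 5).
#' @return An abundance tibble of the same shape with real-valued entries.
#' @export
relative_abundance <- function(counts, totals = NULL, min_count = 5) {
  check_abundance_tbl(counts, "counts")
  vals <- abundance_values(counts)
  if (any(vals < 0)) abort("counts must be nonnegative")
  if (is.null(totals)) {
    totals <- colSums(vals)
  } else {
    miss <- setdiff(colnames(vals), names(totals))
    if (length(miss)) {
      abort(sprintf("totals missing for sample(s): %s", paste(miss, collapse = ", ")))
    }
    totals <- totals[colnames(vals)]
  }
  if (any(totals <= 0)) {
    abort(sprintf("sample total is zero for: %s",
                  paste(colnames(vals)[totals <= 0], collapse = ", ")))
  }
  if (any(colSums(vals) > totals + 1e-9)) {
    abort("per-sample totals smaller than the column sums of the count table")
  }
  rel <- sweep(vals, 2, totals, "/")
  rel[vals < min_count] <- 0
  abundance_tibble(rel, counts$var_type)
}

#' Drop sparse OTU vectors
#'
#' Removes OTU rows observed in fewer than `min_nonzero` samples; such
#' vectors produce spuriously high association scores because their binned
#' distributions are dominated by zeros. Environmental-factor rows are never
#' removed. Row order is preserved.
#'
#' @param matrix An abundance tibble.
#' @param min_nonzero Minimum number of nonzero entries an OTU row must have
#'   to be kept (default 3).
#' @return The filtered abundance tibble.
#' @export
filter_sparse <- function(matrix, min_nonzero = 3) {
  check_abundance_tbl(matrix)
  vals <- abundance_values(matrix)
  nz <- rowSums(vals != 0)
  keep <- matrix$var_type != "OTU" | nz >= min_nonzero
  matrix[keep, ]
}

#' Zero-mean normalization of every variable vector
#'
#' Transforms each row to mean 0 and standard deviation 1 (population SD,
#' i.e. divisor S). Association scores computed downstream with equal-width
#' binning are invariant under this affine transform; normalizing
#' nevertheless puts OTU and environmental rows on one documented scale.
#'
#' @param matrix An abundance tibble; every row must have at least two
#'   distinct values.
#' @return The normalized abundance tibble.
#' @export
zero_mean_normalize <- function(matrix) {
  check_abundance_tbl(matrix)
  vals <- abundance_values(matrix)
  mu <- rowMeans(vals)
  centered <- vals - mu
  sdev <- sqrt(rowMeans(centered^2))
  if (any(sdev == 0)) {
    abort(sprintf("constant row(s) cannot be normalized: %s (filter them first)",
                  paste(matrix$variable[sdev == 0], collapse = ", ")))
  }
  abundance_tibble(centered / sdev, matrix$var_type)
}

#' Stack OTU and environmental tables into one abundance tibble
#'
#' @param otu,env Abundance tibbles over the same samples (env may be NULL).
#' @return The row-bound abundance tibble, OTU rows first.
#' @export
bind_abundance <- function(otu, env = NULL) {
  check_abundance_tbl(otu, "otu")
  if (is.null(env)) return(otu)
  check_abundance_tbl(env, "env")
  if (!setequal(sample_cols(otu), sample_cols(env))) {
    abort("otu and env tables cover different samples")
  }
  dplyr::bind_rows(otu, env[, names(otu)])
}
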