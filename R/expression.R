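# Differential expression for the knockdown experiment: low-count filter,
# NB Wald test (shared machinery), and threshold-based DE classification.

#' Remove genes with any zero count
#'
#' Keeps only genes with more than zero reads in every sample; the number of
#' removed genes is recorded in the `n_removed` attribute.
#'
#' @param counts Integer matrix (genes x samples).
#' @return Filtered matrix.
#' @export
filter_low_counts <- function(counts) {
  stopifnot(is.matrix(counts))
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) warning("no gene passed the all-samples > 0 filter")
  out <- counts[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Negative-binomial differential expression test
#'
#' Median-of-ratios size factors, then the shared negative-binomial Wald test
#' (see [nb_group_test()]) with Benjamini-Hochberg q-values; `log2fc` is
#' `alt` versus `ref`.
#'
#' @param counts Integer matrix (genes x samples), typically pre-filtered
#'   with [filter_low_counts()].
#' @param groups Group label per sample.
#' @param ref,alt Reference and alternative group labels.
#' @param size_factors Optional fixed size factors (estimated when NULL).
#' @return data.frame: `gene_id`, `base_mean`, `log2fc`, `lfc_se`, `stat`,
#'   `p_value`, `q_value`.
#' @export
de_test <- function(counts, groups, ref = "control", alt = "knockdown",
                    size_factors = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  res <- nb_wald_test(counts, groups, ref, alt, size_factors)
  cbind(data.frame(gene_id = rownames(counts), stringsAsFactors = FALSE), res)
}

#' Classify differential-expression results
#'
#' Applies the strict thresholds: `up` when `q < q_max` and
#' `log2fc > lfc_min`, `down` symmetrically, otherwise `ns`.
#'
#' @param results Output of [de_test()].
#' @param q_max Adjusted p-value threshold (strict `<`).
#' @param lfc_min Absolute log2 fold-change threshold (strict `>`).
#' @return `results` with a `call` column.
#' @export
classify_de <- function(results, q_max = 0.05, lfc_min = 0.5) {
  call <- rep("ns", nrow(results))
  call[results$q_value < q_max & results$log2fc > lfc_min] <- "up"
  call[results$q_value < q_max & results$log2fc < -lfc_min] <- "down"
  results$call <- call
  results
}
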