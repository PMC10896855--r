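# End-to-end differential-accessibility pipeline on in-memory inputs.

#' Run the differential-accessibility pipeline
#'
#' Executes the full chain on a synthetic (or similarly structured) dataset:
#' fragments -> Tn5 insertion events -> per-sample peak calls -> reproducible
#' consensus -> enhancer-mark subset -> per-region counts -> negative-binomial
#' group test -> feature/nearest-gene annotation -> RNA-seq DE integration.
#'
#' @param ds Dataset as from [synthetic_dataset()]: needs `fragments`,
#'   `groups`, `genome`, `marks`, and optionally `rna`.
#' @param bin_width Peak-caller bin width (bases).
#' @param flank Pseudo-read half-width for insertion recentring (the 150-base
#'   read convention at the default 75).
#' @param min_support_per_group Consensus support rule.
#' @param alpha Raw p threshold for differential accessibility.
#' @param q_max,lfc_min DE thresholds for the expression integration.
#' @param ref,alt Group labels (accessibility log2fc is `alt` vs `ref`).
#' @return List: `insertions`, `peaks`, `consensus`, `counts`
#'   (`region_counts`), `dar` (tested, annotated, integrated table), `de`
#'   (classified expression results or NULL), `dropped_insertions`.
#' @export
run_dar_pipeline <- function(ds, bin_width = 300, flank = 75,
                             min_support_per_group = 2, alpha = 0.05,
                             q_max = 0.05, lfc_min = 0.5,
                             ref = "naive", alt = "cci") {
  cl <- ds$genome$chrom_lengths
  insertions <- lapply(ds$fragments, fragments_to_insertions, chrom_lengths = cl)
  dropped <- vapply(insertions, function(x) attr(x, "n_dropped"), numeric(1))
  peaks <- lapply(names(insertions), function(s)
    call_peaks_simple(insertions[[s]], cl, bin_width = bin_width,
                      sample_id = s))
  names(peaks) <- names(insertions)
  consensus <- reproducible_consensus(peaks, ds$groups,
                                      min_support_per_group = min_support_per_group)
  consensus <- subset_by_mark(consensus, ds$marks)
  rc <- count_matrix(consensus, insertions, ds$groups)
  rc <- estimate_size_factors(rc)
  dar <- nb_group_test(rc, ref = ref, alt = alt, alpha = alpha)
  dar <- annotate_dars(dar, ds$genome$genes, ds$genome$exons)
  de <- NULL
  if (!is.null(ds$rna)) {
    filt <- filter_low_counts(ds$rna$counts)
    de <- classify_de(de_test(filt, ds$rna$groups, ref = ref, alt = alt),
                      q_max = q_max, lfc_min = lfc_min)
    dar <- integrate_expression(dar, de)
  }
  list(insertions = insertions, peaks = peaks, consensus = consensus,
       counts = rc, dar = dar, de = de, dropped_insertions = dropped)
}
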