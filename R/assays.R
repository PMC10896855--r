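# Deterministic calculators for reporter-assay and ChIP-qPCR arithmetic.

#' Luciferase relative activity
#'
#' Each well's activity is Firefly luminescence normalized to the Renilla
#' co-transfection control; a construct's fold activity is its mean ratio
#' over the empty-vector mean ratio. SEM is propagated from the construct
#' replicates only (the conventional "mean fold +/- SEM" presentation). Wells
#' with non-positive Renilla are excluded.
#'
#' @param wells data.frame with `construct_id`, `firefly`, `renilla`.
#' @param empty_id Construct id of the empty-vector control.
#' @return data.frame per non-control construct: `construct_id`, `n`,
#'   `fold`, `sem`.
#' @export
relative_activity <- function(wells, empty_id = "empty") {
  stopifnot(all(c("construct_id", "firefly", "renilla") %in% names(wells)))
  bad <- wells$renilla <= 0
  if (any(bad)) {
    warning(sum(bad), " well(s) with non-positive Renilla excluded")
    wells <- wells[!bad, , drop = FALSE]
  }
  if (!any(wells$construct_id == empty_id))
    stop("no empty-vector wells ('", empty_id, "')")
  ratio <- wells$firefly / wells$renilla
  ref <- mean(ratio[wells$construct_id == empty_id])
  ids <- setdiff(unique(wells$construct_id), empty_id)
  do.call(rbind, lapply(ids, function(id) {
    r <- ratio[wells$construct_id == id]
    data.frame(construct_id = id, n = length(r), fold = mean(r) / ref,
               sem = if (length(r) > 1) sd(r) / sqrt(length(r)) / ref else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' ChIP-qPCR percent input
#'
#' Adjusts the input Ct for its dilution (`ct' = ct_input - log2(1/dilution)`)
#' and expresses the immunoprecipitated DNA as a percentage of input:
#' `100 * 2^(ct' - ct_ip)`. Assumes amplification efficiency 2.
#'
#' @param ct_ip Ct of the IP (or IgG) reaction.
#' @param ct_input Ct of the diluted input reaction.
#' @param input_dilution_fraction Input dilution as a fraction in `(0, 1]`
#'   (e.g. 0.01 for a 1% input).
#' @return Percent input (vectorized).
#' @examples
#' percent_input(25, 20, 0.01)  # ~0.0312 %
#' @export
percent_input <- function(ct_ip, ct_input, input_dilution_fraction) {
  stopifnot(all(ct_ip > 0), all(ct_input > 0),
            all(input_dilution_fraction > 0 & input_dilution_fraction <= 1))
  ct_adj <- ct_input - log2(1 / input_dilution_fraction)
  100 * 2^(ct_adj - ct_ip)
}

#' Fold enrichment over the IgG control
#'
#' Ratio of IP percent-input to IgG percent-input; with replicate vectors the
#' per-replicate folds are summarized as mean +/- SEM.
#'
#' @param ip_percent,igg_percent Percent-input values (equal length).
#' @return List: `fold` (per replicate), `mean`, `sem` (NA for a single
#'   replicate).
#' @export
fold_enrichment <- function(ip_percent, igg_percent) {
  stopifnot(length(ip_percent) == length(igg_percent))
  if (any(igg_percent <= 0))
    stop("IgG percent input must be positive; check the no-template control")
  fold <- ip_percent / igg_percent
  list(fold = fold, mean = mean(fold),
       sem = if (length(fold) > 1) sd(fold) / sqrt(length(fold)) else NA_real_)
}
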