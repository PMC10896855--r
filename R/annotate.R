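# Feature classification, nearest-gene annotation, and integration of
# differential accessibility with differential expression direction.

#' Classify regions by genomic feature
#'
#' Assigns each region exactly one class by its midpoint, with priority
#' promoter > exon > intron > intergenic. The promoter is a strand-oriented
#' window around the TSS (default 1000 bp upstream to 100 bp downstream); a
#' midpoint inside any gene's promoter window is a promoter regardless of
#' exon overlap elsewhere.
#'
#' @param regions Interval table.
#' @param genes Gene model table (`gene_id`, `chrom`, `tss`, `tes`, `strand`).
#' @param exons Optional exon table (`gene_id`, `chrom`, `start`, `end`);
#'   when NULL every gene body counts as exonic.
#' @param promoter_window Length-2 numeric `c(upstream, downstream)` relative
#'   to the TSS (both non-negative).
#' @return Character vector of classes.
#' @export
classify_feature <- function(regions, genes, exons = NULL,
                             promoter_window = c(1000, 100)) {
  validate_intervals(regions)
  stopifnot(length(promoter_window) == 2, all(promoter_window >= 0))
  mid <- floor((regions$start + regions$end) / 2)
  out <- rep("intergenic", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    g <- genes[genes$chrom == regions$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    rel <- ifelse(g$strand == "-", g$tss - mid[i], mid[i] - g$tss)
    if (any(rel >= -promoter_window[1] & rel <= promoter_window[2])) {
      out[i] <- "promoter"
      next
    }
    lo <- pmin(g$tss, g$tes); hi <- pmax(g$tss, g$tes)
    inside <- mid[i] >= lo & mid[i] <= hi
    if (!any(inside)) next
    if (is.null(exons)) { out[i] <- "exon"; next }
    e <- exons[exons$chrom == regions$chrom[i] &
               exons$gene_id %in% g$gene_id[inside], , drop = FALSE]
    out[i] <- if (nrow(e) > 0 && any(mid[i] >= e$start & mid[i] < e$end))
      "exon" else "intron"
  }
  out
}

#' Annotate differential regions with features and nearest genes
#'
#' Convenience wrapper combining [classify_feature()] and [nearest_tss()].
#'
#' @param dars Differential result table (from [nb_group_test()]).
#' @param genes Gene model table.
#' @param exons Optional exon table.
#' @param promoter_window Promoter window (see [classify_feature()]).
#' @return `dars` with `feature_class`, `nearest_gene`, `tss_distance`.
#' @export
annotate_dars <- function(dars, genes, exons = NULL,
                          promoter_window = c(1000, 100)) {
  dars$feature_class <- classify_feature(dars, genes, exons, promoter_window)
  nn <- nearest_tss(dars, genes)
  dars$nearest_gene <- nn$gene_id
  dars$tss_distance <- nn$tss_distance
  dars
}

#' Integrate accessibility with expression direction
#'
#' Joins each annotated differential region to the differential-expression
#' call of its nearest gene and derives the concordance class: a region with
#' increased accessibility near an upregulated gene is `acc_up_expr_up`,
#' decreased/down is `acc_down_expr_down`, significant but opposite calls are
#' `discordant`, anything else `none`. Genes absent from the expression table
#' are marked `absent`.
#'
#' @param dars Annotated differential regions (see [annotate_dars()]).
#' @param de_table data.frame with `gene_id` and `call` in
#'   `{up, down, ns}` (e.g. from [classify_de()]).
#' @return `dars` with `expression` and `concordance` columns.
#' @export
integrate_expression <- function(dars, de_table) {
  stopifnot(all(c("direction", "nearest_gene") %in% names(dars)),
            all(c("gene_id", "call") %in% names(de_table)))
  expr <- de_table$call[match(dars$nearest_gene, de_table$gene_id)]
  expr[is.na(expr)] <- "absent"
  conc <- rep("none", nrow(dars))
  conc[dars$direction == "increased" & expr == "up"] <- "acc_up_expr_up"
  conc[dars$direction == "decreased" & expr == "down"] <- "acc_down_expr_down"
  conc[dars$direction == "increased" & expr == "down"] <- "discordant"
  conc[dars$direction == "decreased" & expr == "up"] <- "discordant"
  dars$expression <- expr
  dars$concordance <- conc
  dars
}

#' Count concordant region/gene pairs
#'
#' Regions may share a nearest gene, so distinct-gene counts are at most the
#' region counts (the shape behind statements like "109 regions near 79
#' genes").
#'
#' @param annotated Output of [integrate_expression()].
#' @return data.frame with one row per concordance class: `n_regions` and
#'   `n_genes` (distinct nearest genes).
#' @export
concordance_counts <- function(annotated) {
  cls <- c("acc_up_expr_up", "acc_down_expr_down", "discordant", "none")
  do.call(rbind, lapply(cls, function(cc) {
    sub <- annotated[annotated$concordance == cc, , drop = FALSE]
    data.frame(concordance = cc, n_regions = nrow(sub),
               n_genes = length(unique(sub$nearest_gene[!is.na(sub$nearest_gene)])),
               stringsAsFactors = FALSE)
  }))
}

#' Summary table of annotated differential regions
#'
#' Cross-tabulates feature class by direction (and appends per-class totals);
#' the numbers a results section reports, e.g. how many promoters gained or
#' lost accessibility.
#'
#' @param annotated Annotated (optionally expression-integrated) region table.
#' @return data.frame with `feature_class`, `increased`, `decreased`, `ns`,
#'   `total`.
#' @export
summarize_counts <- function(annotated) {
  cls <- c("promoter", "exon", "intron", "intergenic")
  dirs <- c("increased", "decreased", "ns")
  rows <- lapply(cls, function(fc) {
    sub <- annotated[annotated$feature_class == fc, , drop = FALSE]
    cnt <- vapply(dirs, function(d) sum(sub$direction == d), numeric(1))
    data.frame(feature_class = fc, t(cnt), total = nrow(sub))
  })
  out <- do.call(rbind, rows)
  names(out)[2:4] <- dirs
  out
}

#' Percentage of a whole, as printed in reports
#'
#' The summary-report arithmetic used for statements like "58,446 (27.6%) of
#' these 211,440 regions overlapped".
#'
#' @param part,whole Non-negative counts, `whole > 0`.
#' @param digits Decimal places to round to.
#' @return `100 * part / whole`, rounded.
#' @export
pct_of <- function(part, whole, digits = 1) {
  stopifnot(whole > 0, part >= 0)
  round(100 * part / whole, digits)
}
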