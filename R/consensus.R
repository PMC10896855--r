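# H3K4me1-constrained reproducible consensus regions, per-region insertion
# counting, normalization and the negative-binomial differential test.

#' Reproducible consensus accessibility regions
#'
#' Candidate loci are the merged union of all samples' peaks. A locus is
#' supported in a sample when at least one of that sample's peaks overlaps it;
#' a locus is kept when it reaches `min_support_per_group` supporting samples
#' in every group (`mode = "each_group"`, the stringent rule requiring a peak
#' in e.g. both injured replicates and 2 of 3 naive replicates) or in at least
#' one group (`mode = "any_group"`).
#'
#' @param peak_sets Named list of per-sample peak interval tables.
#' @param groups Character vector (same length/names as `peak_sets`) of group
#'   labels.
#' @param min_support_per_group Minimum supporting samples per group.
#' @param mode `"each_group"` or `"any_group"`.
#' @return Interval table of kept loci with a `support` matrix attribute
#'   (loci x samples, logical) and per-group support-count columns.
#' @export
reproducible_consensus <- function(peak_sets, groups,
                                   min_support_per_group = 2,
                                   mode = c("each_group", "any_group")) {
  mode <- match.arg(mode)
  stopifnot(length(peak_sets) == length(groups), length(peak_sets) > 0)
  if (any(table(groups) < min_support_per_group))
    stop("every group needs at least min_support_per_group samples")
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("sample", seq_along(peak_sets))
  loci <- merge_overlapping(do.call(rbind, lapply(peak_sets, function(p)
    p[, c("chrom", "start", "end"), drop = FALSE])))
  support <- vapply(peak_sets, function(p) {
    hit <- rep(FALSE, nrow(loci))
    ov <- overlap_query(loci, p)
    hit[unique(ov$pairs$a_idx)] <- TRUE
    hit
  }, logical(nrow(loci)))
  support <- matrix(support, nrow = nrow(loci),
                    dimnames = list(NULL, names(peak_sets)))
  counts_by_group <- vapply(unique(groups), function(g)
    rowSums(support[, groups == g, drop = FALSE]), numeric(nrow(loci)))
  counts_by_group <- matrix(counts_by_group, nrow = nrow(loci),
                            dimnames = list(NULL, unique(groups)))
  keep <- if (mode == "each_group")
    rowSums(counts_by_group >= min_support_per_group) == ncol(counts_by_group)
  else
    rowSums(counts_by_group >= min_support_per_group) >= 1
  out <- loci[keep, , drop = FALSE]
  for (g in colnames(counts_by_group))
    out[[paste0("support_", g)]] <- counts_by_group[keep, g]
  rownames(out) <- NULL
  attr(out, "support") <- support[keep, , drop = FALSE]
  out
}

#' Restrict consensus regions to an enhancer-mark footprint
#'
#' Keeps regions overlapping (>= 1 bp) a merged set of H3K4me1-enriched
#' regions, the step that turns generic accessible chromatin into candidate
#' cis-regulatory elements. The overlapped fraction of each kept region is
#' recorded.
#'
#' @param consensus Interval table of consensus regions.
#' @param mark_regions Interval table of mark (e.g. H3K4me1) regions.
#' @return Subset of `consensus` with column `mark_overlap_frac`.
#' @export
subset_by_mark <- function(consensus, mark_regions) {
  validate_intervals(consensus)
  if (nrow(mark_regions) == 0) {
    warning("empty mark region set: no consensus region survives")
    out <- consensus[0, , drop = FALSE]
    out$mark_overlap_frac <- numeric(0)
    return(out)
  }
  marks <- merge_overlapping(mark_regions)
  ov <- overlap_query(consensus, marks)
  if (nrow(ov$pairs) == 0) {
    out <- consensus[0, , drop = FALSE]
    out$mark_overlap_frac <- numeric(0)
    return(out)
  }
  bp <- tapply(ov$pairs$overlap, ov$pairs$a_idx, sum)
  idx <- as.integer(names(bp))
  out <- consensus[idx, , drop = FALSE]
  out$mark_overlap_frac <- as.numeric(bp) / interval_width(out)
  rownames(out) <- NULL
  out
}

#' Count insertion events per consensus region
#'
#' A region's count for a sample is the number of insertion positions with
#' `start <= pos < end` (half-open, consistent with single-base bin
#' assignment).
#'
#' @param consensus Interval table of regions.
#' @param event_list Named list of per-sample insertion event data.frames.
#' @param groups Group label per sample.
#' @return A `region_counts` object: list with `regions`, integer `counts`
#'   (regions x samples), `groups`, and `size_factors` (NULL until estimated).
#' @export
count_matrix <- function(consensus, event_list, groups) {
  validate_intervals(consensus)
  stopifnot(length(event_list) == length(groups))
  if (is.null(names(event_list)))
    names(event_list) <- paste0("sample", seq_along(event_list))
  counts <- vapply(event_list, function(ev) {
    n <- integer(nrow(consensus))
    for (ch in unique(consensus$chrom)) {
      ri <- which(consensus$chrom == ch)
      pos <- ev$pos[ev$chrom == ch]
      if (length(pos) == 0) next
      pts <- IRanges::IRanges(start = pos + 1L, width = 1L)
      n[ri] <- IRanges::countOverlaps(.to_iranges(consensus[ri, ]), pts)
    }
    n
  }, integer(nrow(consensus)))
  counts <- matrix(counts, nrow = nrow(consensus),
                   dimnames = list(region_ids(consensus), names(event_list)))
  structure(list(regions = consensus, counts = counts,
                 groups = setNames(as.character(groups), names(event_list)),
                 size_factors = NULL),
            class = "region_counts")
}

region_ids <- function(regions)
  sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)

#' @export
print.region_counts <- function(x, ...) {
  cat(sprintf("region_counts: %d regions x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' The standard count-normalization: each sample's factor is the median across
#' features of its count divided by the feature's geometric mean, computed
#' over features with all-positive counts, then rescaled so the factors have
#' geometric mean 1. Falls back to total-count ratios (with a warning) when no
#' feature is positive everywhere.
#'
#' @param counts Integer matrix (features x samples) or a `region_counts`.
#' @return Named positive vector of size factors (geometric mean 1); for a
#'   `region_counts` input, the object with `size_factors` filled in.
#' @export
estimate_size_factors <- function(counts) {
  if (inherits(counts, "region_counts")) {
    counts$size_factors <- estimate_size_factors(counts$counts)
    return(counts)
  }
  stopifnot(is.matrix(counts), all(counts >= 0))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    warning("no feature with all-positive counts; using total-count ratios")
    sf <- colSums(counts)
    if (any(sf == 0)) stop("sample with zero total count")
  } else {
    logc <- log(counts[pos, , drop = FALSE])
    loggeo <- rowMeans(logc)
    sf <- exp(apply(logc - loggeo, 2, median))
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

# Shared negative-binomial Wald machinery.
#
# Per feature the normalized counts are modelled NB with a common dispersion
# across groups, estimated by pooled method of moments with a floor. The Wald
# statistic is log2fc over its delta-method standard error, referred to a t
# distribution with n1 + n2 - 2 degrees of freedom (small-sample calibration
# verified by simulation). A 0.5 pseudo-count stabilizes zero group means.
nb_wald_test <- function(counts, groups, ref, alt, size_factors = NULL,
                         disp_floor = 1e-8, pseudo = 0.5) {
  stopifnot(is.matrix(counts), ncol(counts) == length(groups))
  i1 <- which(groups == ref); i2 <- which(groups == alt)
  if (length(i1) < 2 || length(i2) < 2)
    stop("need at least 2 samples per group")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(norm[, i1, drop = FALSE])
  m2 <- rowMeans(norm[, i2, drop = FALSE])
  v1 <- apply(norm[, i1, drop = FALSE], 1, var)
  v2 <- apply(norm[, i2, drop = FALSE], 1, var)
  # pooled MoM: Var(normalized) ~ mu * xi + disp * mu^2, xi = mean(1/sf)
  xi <- mean(1 / size_factors)
  num <- (n1 - 1) * (v1 - m1 * xi) + (n2 - 1) * (v2 - m2 * xi)
  den <- (n1 - 1) * m1^2 + (n2 - 1) * m2^2
  disp <- pmax(ifelse(den > 0, num / den, 0), disp_floor)
  log2fc <- log2((m2 + pseudo) / (m1 + pseudo))
  vlog1 <- xi / ((m1 + pseudo) * n1) + disp / n1
  vlog2 <- xi / ((m2 + pseudo) * n2) + disp / n2
  se <- sqrt(vlog1 + vlog2) / log(2)
  stat <- log2fc / se
  p <- 2 * pt(-abs(stat), df = n1 + n2 - 2)
  allzero <- m1 == 0 & m2 == 0
  p[allzero] <- 1; log2fc[allzero] <- 0; stat[allzero] <- 0
  data.frame(base_mean = (m1 * n1 + m2 * n2) / (n1 + n2),
             log2fc = log2fc, lfc_se = se, stat = stat, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}

#' Negative-binomial differential accessibility test
#'
#' Tests each consensus region for an accessibility difference between groups
#' (injured vs naive). See the methods vignette for the model: normalized
#' counts, pooled method-of-moments dispersion with a floor, Wald test on the
#' log2 group-mean ratio, Benjamini-Hochberg q-values. Following the study's
#' permissive design, `direction` is assigned from the sign of `log2fc`
#' whenever the raw p-value is below `alpha`; q-values are reported alongside.
#'
#' @param rc A `region_counts` object.
#' @param ref,alt Group labels: `log2fc` is `alt` versus `ref`.
#' @param alpha Raw p-value threshold for calling a direction.
#' @return data.frame with one row per region: `region_id`, coordinates,
#'   `base_mean`, `log2fc`, `lfc_se`, `stat`, `p_value`, `q_value`,
#'   `direction` in `{increased, decreased, ns}`.
#' @export
nb_group_test <- function(rc, ref = "naive", alt = "cci", alpha = 0.05) {
  stopifnot(inherits(rc, "region_counts"))
  if (is.null(rc$size_factors)) rc <- estimate_size_factors(rc)
  res <- nb_wald_test(rc$counts, rc$groups, ref, alt, rc$size_factors)
  out <- cbind(data.frame(region_id = rownames(rc$counts),
                          rc$regions[, c("chrom", "start", "end")],
                          stringsAsFactors = FALSE),
               res)
  out$direction <- ifelse(out$p_value < alpha,
                          ifelse(out$log2fc > 0, "increased", "decreased"),
                          "ns")
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps `p.adjust`), with input validation.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return q-values, order-preserving, `q >= p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Sample-level quality control
#'
#' PCA on centred `log2(normalized count + 1)` values (samples as
#' observations), Pearson-correlation heatmap values, and average-linkage
#' hierarchical clustering on `1 - correlation` distance.
#'
#' @param rc A `region_counts` object with >= 3 samples.
#' @return List with `pca` (sample scores), `variance_explained`,
#'   `correlations` (sample x sample), and `tree` (an `hclust`).
#' @export
sample_qc <- function(rc) {
  stopifnot(inherits(rc, "region_counts"))
  if (ncol(rc$counts) < 3) stop("sample_qc needs at least 3 samples")
  if (is.null(rc$size_factors)) rc <- estimate_size_factors(rc)
  lm2 <- log2(sweep(rc$counts, 2, rc$size_factors, "/") + 1)
  if (all(apply(lm2, 1, var) == 0)) stop("constant count matrix: QC degenerate")
  pca <- prcomp(t(lm2), center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  cors <- cor(lm2, method = "pearson")
  tree <- hclust(as.dist(1 - cors), method = "average")
  list(pca = pca$x, variance_explained = ve, correlations = cors, tree = tree)
}
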