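#' @import methods
#' @importFrom stats median p.adjust pnorm pt ppois pbinom phyper prcomp
#'   hclust as.dist cor var sd rnbinom rpois rnorm rlnorm runif quantile
#'   setNames aggregate
#' @importFrom utils read.table write.table head tail
NULL

# Internal coordinate convention: 0-based, half-open [start, end), the BED
# standard. 1-based inclusive coordinates exist only at the parse/format
# boundary (the convention used by genome browsers and in printed spans).

#' Construct a genomic interval table
#'
#' The universal region container used throughout the package: a plain
#' `data.frame` with columns `chrom`, `start`, `end` and optionally `strand`,
#' in 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued vectors; `0 <= start < end` (half-open).
#' @param strand Optional vector over `"+"`, `"-"`, `"."`.
#' @param ... Further equal-length columns carried along (e.g. `name`, `score`).
#' @return A `data.frame` of validated intervals.
#' @examples
#' genomic_intervals("chr1", 0, 100)
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, ...) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  if (!is.null(strand)) df$strand <- as.character(strand)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0)) stop("interval start must be >= 0")
  if (any(df$end <= df$start)) stop("interval width must be positive (end > start)")
  if (!is.null(df$strand) && !all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  invisible(df)
}

#' Interval widths
#' @param intervals Interval table (see [genomic_intervals()]).
#' @return Numeric vector of widths `end - start`.
#' @export
interval_width <- function(intervals) intervals$end - intervals$start

#' Parse a printed region string
#'
#' Parses `"chrN:A-B"` strings (comma thousands-separators allowed, as genome
#' browsers print them) into the internal 0-based half-open convention.
#' Published coordinate spans are almost always 1-based inclusive, so width
#' under `one_based_inclusive` is `B - A + 1`.
#'
#' @param text Region string, e.g. `"chr15:46,281,215-46,281,898"`.
#' @param convention `"one_based_inclusive"` (browser/printed style) or
#'   `"zero_based_half_open"` (BED style).
#' @return A one-row interval table.
#' @examples
#' r <- parse_region_string("chr15:46,281,215-46,281,898")
#' interval_width(r)  # 684
#' @export
parse_region_string <- function(text,
                                convention = c("one_based_inclusive",
                                               "zero_based_half_open")) {
  convention <- match.arg(convention)
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub(",", "", text, fixed = TRUE)
  m <- regmatches(s, regexec("^([^:[:space:]]+):([0-9]+)-([0-9]+)$", s))[[1]]
  if (length(m) != 4L) stop("malformed region string: ", text)
  chrom <- m[2]
  a <- as.numeric(m[3]); b <- as.numeric(m[4])
  if (b < a) stop("region end precedes start: ", text)
  if (convention == "one_based_inclusive") {
    genomic_intervals(chrom, a - 1, b)
  } else {
    if (b == a) stop("zero-width region under half-open convention: ", text)
    genomic_intervals(chrom, a, b)
  }
}

#' Format an interval as a region string
#'
#' Inverse of [parse_region_string()]; returns the canonical comma-free form.
#'
#' @param interval One-row interval table.
#' @param convention Output convention (see [parse_region_string()]).
#' @return Character region string.
#' @export
format_region_string <- function(interval,
                                 convention = c("one_based_inclusive",
                                                "zero_based_half_open")) {
  convention <- match.arg(convention)
  validate_intervals(interval)
  stopifnot(nrow(interval) == 1L)
  if (convention == "one_based_inclusive") {
    sprintf("%s:%d-%d", interval$chrom, interval$start + 1, interval$end)
  } else {
    sprintf("%s:%d-%d", interval$chrom, interval$start, interval$end)
  }
}

# IRanges uses 1-based closed coordinates; these two helpers confine the
# conversion to one place.
.to_iranges <- function(df) IRanges::IRanges(start = df$start + 1L, end = df$end)
.from_iranges <- function(ir, chrom) {
  data.frame(chrom = chrom, start = IRanges::start(ir) - 1,
             end = IRanges::end(ir), stringsAsFactors = FALSE)
}

#' Merge overlapping and book-ended intervals
#'
#' Reduces a set of intervals to the minimal sorted, pairwise-disjoint set
#' covering the same bases. Book-ended intervals (`end == start` of the next)
#' are merged, mirroring common merge semantics for region lists pooled
#' across samples.
#'
#' @param intervals Interval table.
#' @return Sorted disjoint interval table.
#' @examples
#' merge_overlapping(genomic_intervals("chr1", c(0, 5, 20), c(10, 15, 30)))
#' @export
merge_overlapping <- function(intervals) {
  validate_intervals(intervals)
  if (nrow(intervals) == 0)
    return(intervals[, c("chrom", "start", "end")])
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    red <- IRanges::reduce(.to_iranges(d))
    .from_iranges(red, d$chrom[1])
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap query between two interval sets
#'
#' Returns index pairs of intervals sharing at least `min_overlap` bases, and
#' the subset of `a` overlapping anything in `b`. Overlap is computed on the
#' half-open spans, so abutting intervals do not overlap.
#'
#' @param a,b Interval tables.
#' @param min_overlap Minimum shared bases (>= 1).
#' @return List with `pairs` (data.frame `a_idx`, `b_idx`, `overlap`) and
#'   `a_overlapping` (rows of `a` with at least one qualifying partner).
#' @export
overlap_query <- function(a, b, min_overlap = 1) {
  validate_intervals(a); validate_intervals(b)
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  pairs <- data.frame(a_idx = integer(), b_idx = integer(), overlap = numeric())
  if (nrow(a) > 0 && nrow(b) > 0) {
    for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
      ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
      hits <- IRanges::findOverlaps(.to_iranges(a[ia, ]), .to_iranges(b[ib, ]),
                                    minoverlap = as.integer(min_overlap))
      if (length(hits) > 0) {
        qi <- ia[S4Vectors_from(hits)]; si <- ib[S4Vectors_to(hits)]
        ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
        pairs <- rbind(pairs, data.frame(a_idx = qi, b_idx = si, overlap = ov))
      }
    }
  }
  pairs <- pairs[order(pairs$a_idx, pairs$b_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs,
       a_overlapping = a[sort(unique(pairs$a_idx)), , drop = FALSE])
}

# thin wrappers so the IRanges accessor generics resolve without attaching
S4Vectors_from <- function(h) methods::slot(h, "from")
S4Vectors_to <- function(h) methods::slot(h, "to")

#' Nearest transcription start site
#'
#' Assigns each region to the gene whose TSS is closest to the region
#' midpoint. Distance is signed in the gene's orientation: positive when the
#' midpoint lies downstream of the TSS. Ties go to the lexicographically
#' smaller `gene_id`; regions on chromosomes without genes get `NA`.
#'
#' @param regions Interval table.
#' @param genes Gene model table with columns `gene_id`, `chrom`, `tss`,
#'   `tes`, `strand`.
#' @return data.frame with `gene_id` and signed `tss_distance` per region.
#' @export
nearest_tss <- function(regions, genes) {
  validate_intervals(regions)
  n <- nrow(regions)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    tss_distance = rep(NA_real_, n))
  if (n == 0 || is.null(genes) || nrow(genes) == 0) return(out)
  mid <- floor((regions$start + regions$end) / 2)
  for (ch in unique(regions$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[order(g$gene_id), , drop = FALSE]   # tie rule: lower gene_id wins
    ri <- which(regions$chrom == ch)
    d <- outer(mid[ri], g$tss, "-")            # regions x genes
    best <- apply(abs(d), 1, which.min)        # which.min takes first = lowest id
    sgn <- ifelse(g$strand[best] == "-", -1, 1)
    out$gene_id[ri] <- g$gene_id[best]
    out$tss_distance[ri] <- d[cbind(seq_along(ri), best)] * sgn
  }
  out
}
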