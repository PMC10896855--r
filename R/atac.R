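# Tn5 insertion-site processing: footprint correction, recentred pseudo-reads,
# binned coverage, group-average and difference tracks, simplified peak calls.

# Run code under a temporary RNG state so seeded operations do not disturb
# the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Convert aligned fragments to Tn5 insertion events
#'
#' Each sequenced fragment is bounded by two transposition events. Because Tn5
#' inserts as a dimer and duplicates 9 bp, the read 5' ends must be shifted
#' +4 (plus strand) / -5 (minus strand) to sit on the central base of the
#' insertion. Both fragment ends are treated as independent 5' ends: the
#' left end behaves as a plus-strand 5' end at `start`, the right end as a
#' minus-strand 5' end at `end`, giving insertion positions `start + 4` and
#' `end - 5`. Events shifted off the chromosome are dropped and counted.
#'
#' @param fragments Interval table of fragment spans (BED-like).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return data.frame of events (`chrom`, `pos`, `source_strand`) with
#'   attribute `n_dropped` (events lost at chromosome edges).
#' @examples
#' f <- genomic_intervals("chr1", 100, 200)
#' fragments_to_insertions(f, c(chr1 = 1000))$pos  # 104, 195
#' @export
fragments_to_insertions <- function(fragments, chrom_lengths) {
  validate_intervals(fragments)
  if (any(interval_width(fragments) <= 9))
    stop("fragment width must exceed the 9 bp Tn5 duplication")
  ev <- data.frame(
    chrom = rep(fragments$chrom, 2),
    pos = c(fragments$start + 4, fragments$end - 5),
    source_strand = rep(c("+", "-"), each = nrow(fragments)),
    stringsAsFactors = FALSE)
  len <- chrom_lengths[ev$chrom]
  keep <- !is.na(len) & ev$pos >= 0 & ev$pos < len
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Recentre insertion events into fixed-width pseudo-reads
#'
#' Extends each single-base insertion `flank` bases in both directions so the
#' insertion sits at the centre of a `2 * flank` window (150 bp at the
#' default), the form used for peak-calling input and track export. Windows
#' are clipped at chromosome edges; clipped rows are flagged.
#'
#' @param events Insertion events (see [fragments_to_insertions()]).
#' @param chrom_lengths Named chromosome lengths.
#' @param flank Bases added on each side (default 75).
#' @return Interval table with logical column `clipped`.
#' @export
recenter_insertions <- function(events, chrom_lengths, flank = 75) {
  stopifnot(flank >= 0)
  len <- chrom_lengths[events$chrom]
  start <- pmax(events$pos - flank, 0)
  end <- pmin(events$pos + flank, len)
  if (flank == 0) end <- pmin(events$pos + 1, len)   # single-base interval
  out <- data.frame(chrom = events$chrom, start = start, end = unname(end),
                    stringsAsFactors = FALSE)
  out$clipped <- if (flank == 0) rep(FALSE, nrow(out)) else
    unname(start > events$pos - flank | end < events$pos + flank)
  validate_intervals(out)
  out
}

new_binned_track <- function(values, bin_width, chrom_lengths, normalization) {
  structure(list(values = values, bin_width = bin_width,
                 chrom_lengths = chrom_lengths, normalization = normalization),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), bin %d bp, %s; total signal %g\n",
              length(x$values), x$bin_width, x$normalization,
              sum(unlist(x$values))))
  invisible(x)
}

#' Binned insertion coverage
#'
#' Counts insertion events in fixed-width genomic bins (default 300 nt). Each
#' event falls in exactly one bin (`pos %/% bin_width`), so bin totals equal
#' the event count.
#'
#' @param events Insertion events.
#' @param chrom_lengths Named chromosome lengths.
#' @param bin_width Bin size in bases.
#' @return A `binned_track` with `normalization = "raw"`.
#' @export
binned_coverage <- function(events, chrom_lengths, bin_width = 300) {
  stopifnot(bin_width > 0)
  vals <- lapply(names(chrom_lengths), function(ch) {
    nb <- ceiling(chrom_lengths[[ch]] / bin_width)
    pos <- events$pos[events$chrom == ch]
    tabulate(pos %/% bin_width + 1L, nbins = nb)
  })
  names(vals) <- names(chrom_lengths)
  new_binned_track(vals, bin_width, chrom_lengths, "raw")
}

#' Downsample insertion events
#'
#' Uniform sampling without replacement to at most `n_target` events,
#' deterministic under `seed`; used to equalize depth before building
#' browser tracks.
#'
#' @param events Insertion events.
#' @param n_target Target event count (>= 0).
#' @param seed Integer seed (NULL = use current RNG state).
#' @return Subset of `events` (original order preserved).
#' @export
downsample_insertions <- function(events, n_target, seed = NULL) {
  stopifnot(n_target >= 0)
  n <- nrow(events)
  if (n_target >= n) return(events)
  idx <- with_seed(seed, sort(sample.int(n, n_target)))
  out <- events[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group-average coverage track
#'
#' Concatenates insertion events from all samples of a treatment group,
#' downsamples the pool to a common target, and bins the result; the group
#' analogue of a per-sample track.
#'
#' @param event_list List of per-sample event data.frames.
#' @param chrom_lengths Named chromosome lengths.
#' @param n_group_target Pooled events to retain (`Inf` keeps all).
#' @param bin_width Bin size in bases.
#' @param seed Downsampling seed.
#' @return A `binned_track` with `normalization = "group-mean"`.
#' @export
group_average_track <- function(event_list, chrom_lengths,
                                n_group_target = Inf, bin_width = 300,
                                seed = NULL) {
  stopifnot(length(event_list) >= 1)
  pooled <- do.call(rbind, event_list)
  if (is.finite(n_group_target))
    pooled <- downsample_insertions(pooled, n_group_target, seed)
  tr <- binned_coverage(pooled, chrom_lengths, bin_width)
  tr$normalization <- "group-mean"
  tr
}

#' Normalize a track to counts per million
#' @param track A `binned_track`.
#' @return Track rescaled so values sum to 1e6 (zero tracks unchanged).
#' @export
normalize_per_million <- function(track) {
  tot <- sum(unlist(track$values))
  if (tot > 0) track$values <- lapply(track$values, function(v) v * 1e6 / tot)
  track$normalization <- "per-million"
  track
}

#' Difference track between two group tracks
#'
#' Bin-wise `cci - naive`; with both inputs normalized to equal totals (see
#' [normalize_per_million()]) this visualizes where accessibility gained or
#' lost signal after injury. Values may be negative.
#'
#' @param cci,naive `binned_track`s on identical bins.
#' @return A `binned_track` with `normalization = "difference"`.
#' @export
difference_track <- function(cci, naive) {
  stopifnot(inherits(cci, "binned_track"), inherits(naive, "binned_track"))
  if (cci$bin_width != naive$bin_width ||
      !identical(names(cci$values), names(naive$values)) ||
      !identical(lengths(cci$values), lengths(naive$values)))
    stop("difference_track requires identical binning")
  cci$values <- Map(`-`, cci$values, naive$values)
  cci$normalization <- "difference"
  cci
}

#' Simplified Poisson peak caller
#'
#' Tests each bin's insertion count against a Poisson background whose rate is
#' the larger of the genome-wide mean and a local mean over a surrounding
#' window (10 kb by default, MACS-style local lambda with a single level).
#' Upper-tail p-values are Benjamini-Hochberg adjusted genome-wide;
#' significant bins within `merge_gap` bins of each other are merged into one
#' peak. The summit is the centre of the highest-count bin.
#'
#' @param events Insertion events for one sample.
#' @param chrom_lengths Named chromosome lengths.
#' @param bin_width Bin size in bases.
#' @param q_max FDR threshold for significant bins.
#' @param merge_gap Maximum number of intervening non-significant bins to
#'   bridge when merging.
#' @param local_window Width (bases) of the local background window.
#' @param sample_id Label recorded in the peak names.
#' @return narrowPeak-style data.frame (`signal` = max bin count, `pvalue` and
#'   `qvalue` as -log10, `summit_offset` from `start`).
#' @export
call_peaks_simple <- function(events, chrom_lengths, bin_width = 300,
                              q_max = 0.05, merge_gap = 1,
                              local_window = 10000, sample_id = "sample") {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(), strand = character(),
                      signal = numeric(), pvalue = numeric(), qvalue = numeric(),
                      summit_offset = numeric(), stringsAsFactors = FALSE)
  if (nrow(events) == 0) return(empty)
  track <- binned_coverage(events, chrom_lengths, bin_width)
  counts <- unlist(track$values, use.names = FALSE)
  chrom_of <- rep(names(track$values), lengths(track$values))
  bin_of <- unlist(lapply(track$values, seq_along), use.names = FALSE) - 1L
  lambda_global <- sum(counts) / length(counts)
  half <- max(1L, floor(local_window / bin_width / 2))
  lambda_local <- unlist(lapply(track$values, function(v) {
    cs <- cumsum(c(0, v))
    i <- seq_along(v)
    lo <- pmax(i - half, 1L); hi <- pmin(i + half, length(v))
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }), use.names = FALSE)
  lambda <- pmax(lambda_global, lambda_local)
  p <- ppois(counts - 1, lambda, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  sig <- which(q <= q_max & counts > 0)
  if (length(sig) == 0) return(empty)
  peaks <- empty
  for (ch in unique(chrom_of[sig])) {
    si <- bin_of[sig][chrom_of[sig] == ch]
    si <- sort(si)
    grp <- cumsum(c(1, diff(si) > merge_gap + 1))
    for (g in unique(grp)) {
      bins <- si[grp == g]
      span <- bins[1]:bins[length(bins)]
      cnt <- track$values[[ch]][span + 1]
      qg <- q[chrom_of == ch][span + 1]
      pg <- p[chrom_of == ch][span + 1]
      start <- bins[1] * bin_width
      end <- min((bins[length(bins)] + 1) * bin_width, chrom_lengths[[ch]])
      summit_bin <- span[which.max(cnt)]
      summit <- min(summit_bin * bin_width + floor(bin_width / 2), end - 1)
      peaks <- rbind(peaks, data.frame(
        chrom = ch, start = start, end = end, name = "", score = 0,
        strand = ".", signal = max(cnt),
        pvalue = -log10(max(min(pg), 1e-300)),
        qvalue = -log10(max(min(qg), 1e-300)),
        summit_offset = summit - start, stringsAsFactors = FALSE))
    }
  }
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  peaks$name <- sprintf("%s_peak_%d", sample_id, seq_len(nrow(peaks)))
  peaks$score <- round(pmin(1000, 10 * peaks$qvalue))
  rownames(peaks) <- NULL
  peaks
}
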