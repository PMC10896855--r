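# Known-motif scanning and enrichment: PWM construction, exact score-threshold
# computation by discretized convolution, double-stranded log-odds scanning,
# and binomial enrichment of target vs background region sets.

DNA_BASES <- c("A", "C", "G", "T")

#' Build a position weight matrix
#'
#' Converts per-position nucleotide counts (rows A, C, G, T) into a
#' probability matrix, adding a small pseudo-count per cell before
#' normalization so log-odds scores stay finite.
#'
#' @param counts 4 x width numeric matrix (rows named A, C, G, T).
#' @param motif_id,name Identifiers.
#' @param pseudocount Added to each probability cell (default 0.001).
#' @param background Background nucleotide frequencies (length 4, sums to 1).
#' @return A `pwm` object: list with `motif_id`, `name`, `counts`, `prob`,
#'   `background`, `width`.
#' @export
pwm_from_counts <- function(counts, motif_id = "motif", name = motif_id,
                            pseudocount = 0.001,
                            background = rep(0.25, 4)) {
  stopifnot(is.matrix(counts), nrow(counts) == 4, all(counts >= 0),
            length(background) == 4, all(background > 0))
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES
  counts <- counts[DNA_BASES, , drop = FALSE]
  prob <- sweep(counts, 2, colSums(counts), "/")
  prob <- prob + pseudocount
  prob <- sweep(prob, 2, colSums(prob), "/")
  structure(list(motif_id = motif_id, name = name, counts = counts,
                 prob = prob, background = setNames(background / sum(background),
                                                    DNA_BASES),
                 width = ncol(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), width %d, consensus %s\n", x$motif_id, x$name,
              x$width, paste(DNA_BASES[apply(x$prob, 2, which.max)],
                             collapse = "")))
  invisible(x)
}

# per-position log2-odds score matrix (4 x width)
pwm_score_matrix <- function(pwm) log2(sweep(pwm$prob, 1, pwm$background, "/"))

# reverse-complement a pwm (reverse positions, swap A<->T, C<->G)
pwm_revcomp <- function(pwm) {
  rc <- pwm
  flip <- c("T", "G", "C", "A")
  rc$counts <- pwm$counts[flip, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(rc$counts) <- DNA_BASES
  rc$prob <- pwm$prob[flip, rev(seq_len(pwm$width)), drop = FALSE]
  rownames(rc$prob) <- DNA_BASES
  rc$background <- setNames(pwm$background[flip], DNA_BASES)
  rc
}

#' Exact score threshold from the background score distribution
#'
#' Computes the distribution of the PWM log-odds score of a random background
#' sequence exactly, by discretizing per-position scores to multiples of
#' `delta` and convolving across positions, and returns the smallest cutoff
#' whose upper-tail probability does not exceed `threshold_p`.
#'
#' @param pwm A `pwm` object.
#' @param threshold_p Target tail probability in `(0, 1]`.
#' @param background Optional background frequencies (defaults to the PWM's).
#' @param delta Score discretization step in bits.
#' @return Score cutoff (bits); `P(score >= cutoff) <= threshold_p` and
#'   `P(score >= cutoff - delta) > threshold_p` (cutoff is the minimum score
#'   when `threshold_p = 1`).
#' @export
score_threshold_dp <- function(pwm, threshold_p, background = NULL,
                               delta = 0.01) {
  stopifnot(inherits(pwm, "pwm"))
  if (threshold_p <= 0 || threshold_p > 1)
    stop("threshold_p must lie in (0, 1]")
  bg <- if (is.null(background)) pwm$background else
    setNames(background / sum(background), DNA_BASES)
  sm <- round(pwm_score_matrix(pwm) / delta)   # integer scores per cell
  # distribution over integer scores as a named probability vector
  dist <- c(`0` = 1)
  for (j in seq_len(pwm$width)) {
    s <- sm[, j]
    supp <- as.integer(names(dist))
    newsupp <- as.vector(outer(supp, s, "+"))
    neww <- as.vector(outer(unname(dist), unname(bg), "*"))
    agg <- tapply(neww, newsupp, sum)
    dist <- setNames(as.numeric(agg), names(agg))
  }
  supp <- as.integer(names(dist))
  o <- order(supp, decreasing = TRUE)
  tail_p <- cumsum(dist[o])         # P(S >= supp[o])
  sorted <- supp[o]
  ok <- which(tail_p <= threshold_p + 1e-12)
  cutoff_int <- if (length(ok) == 0) sorted[1] + 1L else sorted[max(ok)]
  cutoff_int * delta
}

.encode_seq <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  match(chars, DNA_BASES)   # NA for N or anything else
}

.scan_one_strand <- function(code, sm, cutoff) {
  w <- ncol(sm)
  L <- length(code)
  if (L < w) return(data.frame(pos = integer(), score = numeric()))
  n_win <- L - w + 1
  score <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(w)) {
    b <- code[j:(j + n_win - 1)]
    miss <- is.na(b)
    valid <- valid & !miss
    b[miss] <- 1L
    score <- score + sm[cbind(b, j)]
  }
  hit <- valid & score >= cutoff - 1e-9
  data.frame(pos = which(hit) - 1L, score = score[hit])
}

#' Scan a sequence for PWM hits on both strands
#'
#' Scores every window of the sequence as the sum of per-position
#' `log2(p/background)` terms and reports windows at or above the exact
#' threshold for `threshold_p` (see [score_threshold_dp()]). The reverse
#' strand is scanned with the reverse-complemented matrix, so positions are
#' always forward-strand window starts. Windows containing `N` are skipped.
#'
#' @param sequence Character string over A/C/G/T/N.
#' @param pwm A `pwm` object.
#' @param threshold_p Tail probability defining the hit threshold.
#' @param cutoff Optional precomputed score cutoff (overrides `threshold_p`).
#' @return data.frame of hits: `pos` (0-based window start), `strand`,
#'   `score`.
#' @export
logodds_scan <- function(sequence, pwm, threshold_p = 1e-4, cutoff = NULL) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(cutoff)) cutoff <- score_threshold_dp(pwm, threshold_p)
  code <- .encode_seq(sequence)
  fwd <- .scan_one_strand(code, pwm_score_matrix(pwm), cutoff)
  rev <- .scan_one_strand(code, pwm_score_matrix(pwm_revcomp(pwm)), cutoff)
  out <- rbind(cbind(fwd, strand = rep("+", nrow(fwd))),
               cbind(rev, strand = rep("-", nrow(rev))))
  out <- out[order(out$pos, out$strand), c("pos", "strand", "score")]
  rownames(out) <- NULL
  out
}

#' Extract fixed-size sequence windows centred on regions
#'
#' Pulls a `size`-bp window centred on each region midpoint from the genome
#' (clipped at chromosome ends), the standard preparation for motif analysis
#' of peak sets.
#'
#' @param regions Interval table.
#' @param genome Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param size Window width in bases.
#' @return Character vector of sequences.
#' @export
extract_region_sequences <- function(regions, genome, size = 200) {
  validate_intervals(regions)
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  mid <- floor((regions$start + regions$end) / 2)
  start <- pmax(mid - floor(size / 2), 0)
  vapply(seq_len(nrow(regions)), function(i) {
    s <- genome[[regions$chrom[i]]]
    a <- start[i] + 1
    b <- min(start[i] + size, nchar(s))
    substr(s, a, b)
  }, character(1))
}

#' GC-matched background sampling
#'
#' Samples background sequences from a pool so the sampled GC-content
#' distribution matches the targets' (binned matching), the usual control for
#' nucleotide-composition bias in motif enrichment.
#'
#' @param target_seqs,pool_seqs Character vectors of sequences.
#' @param n Number of background sequences to draw.
#' @param bins Number of GC bins.
#' @param seed Sampling seed.
#' @return Character vector of sampled background sequences.
#' @export
gc_matched_background <- function(target_seqs, pool_seqs,
                                  n = length(target_seqs), bins = 10,
                                  seed = NULL) {
  gc <- function(s) {
    ch <- strsplit(toupper(s), "")
    vapply(ch, function(x) {
      acgt <- x %in% DNA_BASES
      if (!any(acgt)) return(0.5)
      sum(x %in% c("G", "C")) / sum(acgt)
    }, numeric(1))
  }
  gt <- gc(target_seqs); gp <- gc(pool_seqs)
  br <- seq(0, 1, length.out = bins + 1)
  bt <- cut(gt, br, include.lowest = TRUE)
  bp <- cut(gp, br, include.lowest = TRUE)
  with_seed(seed, {
    want <- round(n * as.numeric(table(bt)) / length(gt))
    out <- character(0)
    for (k in seq_len(bins)) {
      avail <- which(as.integer(bp) == k)
      if (length(avail) == 0 || want[k] == 0) next
      take <- sample(avail, min(want[k], length(avail)))
      out <- c(out, pool_seqs[take])
    }
    deficit <- n - length(out)
    if (deficit > 0)
      out <- c(out, pool_seqs[sample.int(length(pool_seqs), deficit,
                                         replace = deficit > length(pool_seqs))])
    out
  })
}

#' Known-motif enrichment of target vs background sequences
#'
#' For each PWM, counts target and background sequences containing at least
#' one double-stranded hit at the `threshold_p` score cutoff and tests target
#' enrichment with a one-sided binomial test using the background hit
#' fraction as the null proportion (the classic known-motif statistic). When
#' the background is an explicit finite set a hypergeometric (Fisher) p-value
#' is reported alongside. q-values are Benjamini-Hochberg across motifs.
#'
#' @param target_seqs,background_seqs Character vectors of sequences.
#' @param pwms Named list of `pwm` objects.
#' @param threshold_p Per-window score tail probability.
#' @return data.frame: `motif_id`, `name`, `n_target`, `n_background`,
#'   `pct_target`, `pct_background`, `p_value`, `p_hyper`, `q_value`.
#' @export
enrichment_test <- function(target_seqs, background_seqs, pwms,
                            threshold_p = 1e-4) {
  if (length(target_seqs) == 0) stop("empty target sequence set")
  if (length(background_seqs) == 0) stop("empty background sequence set")
  rows <- lapply(pwms, function(pw) {
    cutoff <- score_threshold_dp(pw, threshold_p)
    has_hit <- function(seqs) vapply(seqs, function(s)
      nrow(logodds_scan(s, pw, cutoff = cutoff)) > 0, logical(1),
      USE.NAMES = FALSE)
    kt <- sum(has_hit(target_seqs)); nt <- length(target_seqs)
    kb <- sum(has_hit(background_seqs)); nb <- length(background_seqs)
    p0 <- kb / nb
    p <- if (kt == 0) 1 else pbinom(kt - 1, nt, p0, lower.tail = FALSE)
    ph <- phyper(kt - 1, kt + kb, nt + nb - kt - kb, nt, lower.tail = FALSE)
    data.frame(motif_id = pw$motif_id, name = pw$name,
               n_target = kt, n_background = kb,
               pct_target = kt / nt, pct_background = p0,
               p_value = p, p_hyper = ph, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- pmax(bh_adjust(out$p_value), out$p_value)
  rownames(out) <- NULL
  out
}
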