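# Shared fixtures, computed once per test run.

# default-design dataset and its pipeline result (used by several files and
# by the end-to-end checks)
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- synthetic_dataset(synthetic_design(seed = 1L))
    cache
  }
})

default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- run_dar_pipeline(default_dataset())
    cache
  }
})

# random intervals on one toy chromosome
random_intervals <- function(n, chrom_len = 1e5, max_width = 500,
                             chrom = "chrT") {
  start <- floor(runif(n, 0, chrom_len - max_width))
  genomic_intervals(chrom, start, start + ceiling(runif(n, 1, max_width)))
}

# brute-force per-base occupancy mask of an interval set (single chromosome)
base_mask <- function(intervals, chrom_len) {
  m <- logical(chrom_len)
  for (i in seq_len(nrow(intervals)))
    m[(intervals$start[i] + 1):intervals$end[i]] <- TRUE
  m
}

# a sharp test PWM: near-consensus for the given word
consensus_pwm <- function(word, p_major = 0.97, id = "TEST") {
  bases <- strsplit(word, "")[[1]]
  counts <- sapply(bases, function(b) {
    v <- rep((1 - p_major) / 3, 4)
    names(v) <- c("A", "C", "G", "T")
    v[b] <- p_major
    v * 1000
  })
  pwm_from_counts(matrix(counts, nrow = 4,
                         dimnames = list(c("A", "C", "G", "T"), NULL)),
                  motif_id = id)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

revcomp_chr <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}
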