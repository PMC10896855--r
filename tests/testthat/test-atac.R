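cl1 <- c(chr1 = 10000)

test_that("Tn5 footprint shift is +4 on plus ends and -5 on minus ends", {
  f <- genomic_intervals("chr1", 100, 200)
  ev <- fragments_to_insertions(f, cl1)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$pos[ev$source_strand == "+"], 104)
  expect_equal(ev$pos[ev$source_strand == "-"], 195)
  expect_equal(attr(ev, "n_dropped"), 0)
  # conservation minus boundary drops
  f2 <- genomic_intervals("chr1", c(0, 9990), c(50, 10000))
  ev2 <- fragments_to_insertions(f2, cl1)
  expect_equal(nrow(ev2) + attr(ev2, "n_dropped"), 4)
  expect_true(all(ev2$pos >= 0 & ev2$pos < 10000))
  expect_error(fragments_to_insertions(genomic_intervals("chr1", 0, 9), cl1),
               "9 bp")
})

test_that("recentring produces 150-base reads, clipped at edges", {
  ev <- data.frame(chrom = "chr1", pos = c(104, 10, 9990), source_strand = "+")
  rc <- recenter_insertions(ev, cl1, flank = 75)
  expect_equal(rc$start[1], 29)
  expect_equal(rc$end[1], 179)
  expect_equal(interval_width(rc)[1], 150)
  expect_false(rc$clipped[1])
  expect_equal(c(rc$start[2], rc$end[2]), c(0, 85))
  expect_true(rc$clipped[2])
  expect_equal(rc$end[3], 10000)
  # flank 0 degenerates to the single insertion base
  rc0 <- recenter_insertions(ev, cl1, flank = 0)
  expect_equal(interval_width(rc0), rep(1, 3))
})

test_that("binned coverage equals a brute-force histogram and conserves counts", {
  ev <- data.frame(chrom = "chr1", pos = c(10, 310, 320), source_strand = "+")
  tr <- binned_coverage(ev, cl1, bin_width = 300)
  expect_equal(tr$values$chr1[1:2], c(1, 2))
  expect_equal(sum(tr$values$chr1), 3)
  # empty input -> all-zero track of the right length
  tr0 <- binned_coverage(ev[0, ], cl1, bin_width = 300)
  expect_equal(sum(tr0$values$chr1), 0)
  expect_equal(length(tr0$values$chr1), ceiling(10000 / 300))
  # large random instance vs. oracle histogram
  set.seed(11)
  pos <- sample.int(10000, 1e5, replace = TRUE) - 1
  ev2 <- data.frame(chrom = "chr1", pos = pos, source_strand = "+")
  tr2 <- binned_coverage(ev2, cl1, bin_width = 300)
  oracle <- unname(table(factor(pos %/% 300, levels = 0:33)))
  expect_equal(tr2$values$chr1, as.numeric(oracle))
  expect_equal(sum(tr2$values$chr1), 1e5)
})

test_that("downsampling is uniform, seeded and size-exact", {
  ev <- data.frame(chrom = "chr1", pos = 0:9999, source_strand = "+")
  expect_identical(downsample_insertions(ev, 20000, seed = 1), ev)
  expect_equal(nrow(downsample_insertions(ev, 0, seed = 1)), 0)
  s1 <- downsample_insertions(ev, 500, seed = 42)
  expect_identical(s1, downsample_insertions(ev, 500, seed = 42))
  expect_equal(nrow(s1), 500)
  # a region holding 20% of events retains ~20% after halving
  set.seed(3)
  ev2 <- data.frame(chrom = "chr1",
                    pos = c(sample(2000:2999, 2000, TRUE),
                            sample.int(10000, 8000, TRUE) - 1),
                    source_strand = "+")
  fr <- replicate(200, {
    s <- downsample_insertions(ev2, 5000)
    mean(s$pos >= 2000 & s$pos < 3000)
  })
  p0 <- mean(ev2$pos >= 2000 & ev2$pos < 3000)
  expect_lt(abs(mean(fr) - p0), 3 * sqrt(p0 * (1 - p0) / 5000) / sqrt(200) * 10)
})

test_that("group tracks pool samples and difference tracks are antisymmetric", {
  ev <- data.frame(chrom = "chr1", pos = c(10, 310, 320), source_strand = "+")
  # one sample, no downsampling -> identical to its own coverage
  g1 <- group_average_track(list(ev), cl1, bin_width = 300)
  expect_equal(g1$values, binned_coverage(ev, cl1, 300)$values)
  # two identical samples double the raw counts
  g2 <- group_average_track(list(ev, ev), cl1, bin_width = 300)
  expect_equal(g2$values$chr1, 2 * g1$values$chr1)
  # difference semantics
  a <- binned_coverage(ev, cl1, 300)
  b <- binned_coverage(ev[1:2, ], cl1, 300)
  d_ab <- difference_track(a, b)
  d_ba <- difference_track(b, a)
  expect_equal(d_ab$values$chr1, -d_ba$values$chr1)
  expect_equal(difference_track(a, a)$values$chr1, rep(0, 34))
  expect_equal(sum(d_ab$values$chr1), 1)
  expect_error(difference_track(a, binned_coverage(ev, cl1, 200)), "binning")
  # per-million normalization makes totals comparable
  expect_equal(sum(unlist(normalize_per_million(a)$values)), 1e6)
})

test_that("peak caller is calibrated on homogeneous noise and finds planted peaks", {
  set.seed(77)
  cl <- c(chr1 = 1.5e6)  # 5000 bins
  pos <- sample.int(1.5e6, 25000, replace = TRUE) - 1
  ev <- data.frame(chrom = "chr1", pos = pos, source_strand = "+")
  pk <- call_peaks_simple(ev, cl, bin_width = 300, q_max = 0.05)
  # homogeneous background: essentially nothing should pass BH
  sig_bins <- sum((pk$end - pk$start) / 300)
  expect_lte(sig_bins / 5000, 0.05)
  # planted region at 10x the local rate -> exactly one covering peak
  extra <- data.frame(chrom = "chr1",
                      pos = sample(700000:700299, 60, TRUE),
                      source_strand = "+")
  pk2 <- call_peaks_simple(rbind(ev, extra), cl, bin_width = 300)
  hit <- pk2[pk2$start <= 700000 & pk2$end >= 700300, ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$summit_offset >= 0 &
              hit$summit_offset < hit$end - hit$start)
  # empty input -> empty peak set
  expect_equal(nrow(call_peaks_simple(ev[0, ], cl)), 0)
})

test_that("raising q_max never loses peak coverage", {
  set.seed(78)
  cl <- c(chr1 = 3e5)
  ev <- data.frame(chrom = "chr1",
                   pos = c(sample.int(3e5, 5000, TRUE) - 1,
                           sample(100000:100599, 80, TRUE),
                           sample(200000:200299, 25, TRUE)),
                   source_strand = "+")
  p_strict <- call_peaks_simple(ev, cl, q_max = 0.01)
  p_loose <- call_peaks_simple(ev, cl, q_max = 0.10)
  # every strict peak is contained in some loose peak
  for (i in seq_len(nrow(p_strict))) {
    expect_true(any(p_loose$start <= p_strict$start[i] &
                    p_loose$end >= p_strict$end[i]))
  }
})
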