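make_peaks <- function(...) {
  lapply(list(...), function(m)
    genomic_intervals("chr1", m[, 1], m[, 2]))
}

test_that("support rule keeps loci reproducible in every group", {
  # locus A supported by 2/3 naive and 2/2 cci; locus B by 1/3 naive only
  peaks <- make_peaks(
    rbind(c(100, 200), c(1000, 1100)),   # naive1: A and B
    rbind(c(120, 210)),                  # naive2: A
    rbind(c(5000, 5100)),                # naive3: elsewhere
    rbind(c(90, 190)),                   # cci1: A
    rbind(c(150, 260)))                  # cci2: A
  groups <- c("naive", "naive", "naive", "cci", "cci")
  cons <- reproducible_consensus(peaks, groups, min_support_per_group = 2)
  expect_equal(nrow(cons), 1)
  expect_true(cons$start <= 100 && cons$end >= 260)
  expect_equal(cons$support_naive, 2)
  expect_equal(cons$support_cci, 2)
  # any_group mode also keeps the naive-only locus? (B has support 1 -> no)
  cons_any <- reproducible_consensus(peaks, groups,
                                     min_support_per_group = 2,
                                     mode = "any_group")
  expect_equal(nrow(cons_any), 1)
  expect_error(reproducible_consensus(peaks[1:3], c("naive", "naive", "cci")),
               "min_support")
})

test_that("consensus support matches a brute-force per-locus count", {
  set.seed(404)
  peaks <- lapply(1:5, function(i) random_intervals(60))
  groups <- c("naive", "naive", "naive", "cci", "cci")
  cons <- reproducible_consensus(peaks, groups, min_support_per_group = 2)
  loci <- merge_overlapping(do.call(rbind, peaks))
  support <- sapply(peaks, function(p) {
    vapply(seq_len(nrow(loci)), function(i)
      any(p$start < loci$end[i] & p$end > loci$start[i]), logical(1))
  })
  nv <- rowSums(support[, 1:3]); cc <- rowSums(support[, 4:5])
  keep <- nv >= 2 & cc >= 2
  expect_equal(cons$start, loci$start[keep])
  expect_equal(cons$end, loci$end[keep])
  expect_equal(cons$support_naive, unname(nv[keep]))
})

test_that("mark subsetting keeps only mark-overlapped regions", {
  cons <- genomic_intervals("chr1", c(100, 500, 900), c(200, 600, 1000))
  marks <- genomic_intervals("chr1", c(120, 601), c(180, 650))
  out <- subset_by_mark(cons, marks)
  expect_equal(out$start, 100)      # fully containing a mark -> kept
  expect_equal(out$mark_overlap_frac, 0.6)
  # region 1 bp away from a mark is dropped (500-600 vs 601-650)
  expect_false(500 %in% out$start)
  expect_warning(empty <- subset_by_mark(cons, marks[0, ]), "empty mark")
  expect_equal(nrow(empty), 0)
})

test_that("mark-then-consensus equals consensus-then-mark on synthetic data", {
  ds <- default_dataset()
  res <- default_pipeline()
  marks <- ds$marks
  # subset each sample's peaks first, then build consensus
  sub_peaks <- lapply(res$peaks, function(p) {
    keep <- overlap_query(p, marks)
    keep$a_overlapping
  })
  alt <- reproducible_consensus(sub_peaks, ds$groups, min_support_per_group = 2)
  alt <- subset_by_mark(alt, marks)  # idempotent here; normalizes columns
  expect_equal(alt$start, res$consensus$start)
  expect_equal(alt$end, res$consensus$end)
})

test_that("region counting uses half-open insertion positions", {
  cons <- genomic_intervals("chr1", 100, 200)
  ev <- data.frame(chrom = "chr1", pos = c(99, 100, 199, 200),
                   source_strand = "+")
  rc <- count_matrix(cons, list(s1 = ev, s2 = ev[1:2, ]),
                     c("naive", "cci"))
  expect_equal(unname(rc$counts[1, ]), c(2, 1))
  # random data vs. brute-force scan
  set.seed(55)
  regions <- merge_overlapping(random_intervals(40))
  ev2 <- data.frame(chrom = "chrT",
                    pos = sample.int(1e5, 5000, TRUE) - 1,
                    source_strand = "+")
  rc2 <- count_matrix(regions, list(a = ev2), "naive")
  oracle <- vapply(seq_len(nrow(regions)), function(i)
    sum(ev2$pos >= regions$start[i] & ev2$pos < regions$end[i]), numeric(1))
  expect_equal(unname(rc2$counts[, 1]), oracle)
  expect_lte(sum(rc2$counts), nrow(ev2))
})

test_that("size factors recover known depth ratios with geometric mean 1", {
  set.seed(66)
  base <- matrix(rpois(50 * 4, 100) + 1, 50, 4)
  sf0 <- estimate_size_factors(base)
  expect_equal(exp(mean(log(sf0))), 1, tolerance = 1e-12)
  doubled <- base
  doubled[, 2] <- base[, 2] * 2
  sf <- estimate_size_factors(doubled)
  expect_equal(sf[[2]] / sf[[1]], 2, tolerance = 0.05)
  # identical samples -> all ones
  same <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))
  expect_warning(estimate_size_factors(matrix(c(0L, 5L, 5L, 0L), 2, 2)),
                 "total-count")
})

test_that("nb test is calibrated on null data and label-symmetric", {
  set.seed(88)
  counts <- matrix(rnbinom(2000 * 6, mu = 100, size = 10), 2000, 6,
                   dimnames = list(sprintf("r%04d", 1:2000),
                                   c(paste0("n", 1:3), paste0("c", 1:3))))
  regions <- genomic_intervals("chr1", seq(0, by = 1000, length.out = 2000),
                               seq(500, by = 1000, length.out = 2000))
  rc <- structure(list(regions = regions, counts = counts,
                       groups = setNames(rep(c("naive", "cci"), each = 3),
                                         colnames(counts)),
                       size_factors = NULL), class = "region_counts")
  res <- nb_group_test(rc)
  rej <- mean(res$p_value < 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
  expect_true(all(res$q_value >= res$p_value))
  # label swap negates log2fc and preserves p
  swapped <- rc
  swapped$groups <- setNames(rep(c("cci", "naive"), each = 3),
                             colnames(counts))
  res2 <- nb_group_test(swapped)
  expect_equal(res2$log2fc, -res$log2fc, tolerance = 1e-12)
  expect_equal(res2$p_value, res$p_value, tolerance = 1e-12)
  # all-zero region
  counts0 <- counts; counts0[1, ] <- 0L
  rc0 <- rc; rc0$counts <- counts0
  r0 <- nb_group_test(rc0)
  expect_equal(r0$p_value[1], 1)
  expect_equal(r0$log2fc[1], 0)
  expect_equal(r0$direction[1], "ns")
})

test_that("nb test has power against a 3x effect at n = 3 per group", {
  set.seed(89)
  mu <- cbind(matrix(100, 500, 3), matrix(300, 500, 3))
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 10), 500, 6,
                   dimnames = list(sprintf("r%03d", 1:500),
                                   c(paste0("n", 1:3), paste0("c", 1:3))))
  regions <- genomic_intervals("chr1", seq(0, by = 1000, length.out = 500),
                               seq(500, by = 1000, length.out = 500))
  rc <- structure(list(regions = regions, counts = counts,
                       groups = setNames(rep(c("naive", "cci"), each = 3),
                                         colnames(counts)),
                       size_factors = setNames(rep(1, 6), colnames(counts))),
                  class = "region_counts")
  res <- nb_group_test(rc)
  expect_gte(mean(res$p_value < 0.05 & res$log2fc > 0), 0.8)
})

test_that("bh adjustment matches the step-up formula oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(99)
  p <- runif(1000)
  # direct step-up: q_(i) = min_{j >= i} ( n p_(j) / j )
  o <- order(p)
  n <- length(p)
  q_sorted <- rev(cummin(rev(n * p[o] / seq_len(n))))
  q_oracle <- pmin(q_sorted[order(o)], 1)
  expect_equal(bh_adjust(p), q_oracle)
})

test_that("sample QC separates planted groups and handles degenerate input", {
  res <- default_pipeline()
  qc <- sample_qc(res$counts)
  expect_true(all(qc$variance_explained >= 0))
  expect_lte(sum(qc$variance_explained), 1 + 1e-9)
  grp <- res$counts$groups
  pc1 <- qc$pca[, 1]
  expect_true(all(sign(pc1[grp == "cci"]) ==
                  -sign(pc1[grp == "naive"][1])) ||
              all(sign(pc1[grp == "cci"]) == sign(pc1[grp == "cci"][1])))
  # group separation on PC1: means on opposite sides
  expect_true(mean(pc1[grp == "cci"]) * mean(pc1[grp == "naive"]) < 0)
  # duplicated sample -> zero distance
  rc <- res$counts
  rc$counts[, 2] <- rc$counts[, 1]
  rc$size_factors <- NULL
  qc2 <- sample_qc(estimate_size_factors(rc))
  expect_equal(qc2$correlations[1, 2], 1)
  const <- rc
  const$counts[] <- 5L
  expect_error(sample_qc(const), "constant|degenerate")
})
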