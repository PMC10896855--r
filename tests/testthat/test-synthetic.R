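test_that("generators are deterministic under the design seed", {
  d <- synthetic_design(depth = 5e3, n_accessible_regions = 50, n_genes = 40,
                        seed = 9L)
  g1 <- generate_genome_and_genes(d)
  g2 <- generate_genome_and_genes(d)
  expect_identical(g1, g2)
  tr1 <- synthetic_truth(d, g1)
  expect_identical(tr1, synthetic_truth(d, g2))
  f1 <- generate_atac_fragments(d, tr1, g1)
  expect_identical(f1, generate_atac_fragments(d, tr1, g1))
  expect_identical(generate_rna_counts(d, tr1, g1),
                   generate_rna_counts(d, tr1, g1))
  expect_identical(generate_tf_array(d, tr1), generate_tf_array(d, tr1))
})

test_that("gene placement respects bounds and an empty gene table is valid", {
  d <- synthetic_design(n_genes = 200, genome_length = 2.5e6)
  g <- generate_genome_and_genes(d)
  expect_equal(nrow(g$genes), 200)
  lens <- g$chrom_lengths[g$genes$chrom]
  expect_true(all(g$genes$tss >= 0 & g$genes$tss < lens))
  expect_true(all(g$genes$tes >= 0 & g$genes$tes < lens))
  expect_true(all(g$exons$start < g$exons$end))
  # genes do not overlap at all (stronger than per-strand)
  for (ch in names(g$chrom_lengths)) {
    gg <- g$genes[g$genes$chrom == ch, ]
    lo <- pmin(gg$tss, gg$tes); hi <- pmax(gg$tss, gg$tes)
    o <- order(lo)
    expect_true(all(lo[o][-1] > hi[o][-length(o)]))
  }
  g0 <- generate_genome_and_genes(synthetic_design(n_genes = 0))
  expect_equal(nrow(g0$genes), 0)
  expect_equal(length(g0$chrom_lengths), 2)
  expect_error(generate_genome_and_genes(
    synthetic_design(n_genes = 200, genome_length = 1e5)), "too small")
})

test_that("fragment totals equal depth and planted effect shows in counts", {
  ds <- default_dataset()
  expect_true(all(vapply(ds$fragments, nrow, numeric(1)) == ds$design$depth))
  expect_true(all(vapply(ds$fragments, function(f)
    all(f$end - f$start > 9), logical(1))))
})

test_that("planted group effect reproduces the design ratio empirically", {
  # >= 50 planted regions for the Monte-Carlo mean; effect 2x
  d <- synthetic_design(n_accessible_regions = 300, frac_dar = 0.4,
                        dar_effect = 2, depth = 2e5, seed = 17L)
  g <- generate_genome_and_genes(d)
  tr <- synthetic_truth(d, g)
  fr <- generate_atac_fragments(d, tr, g)
  ins <- lapply(fr, fragments_to_insertions, chrom_lengths = g$chrom_lengths)
  up <- tr$regions[tr$regions$direction == 1L, ]
  expect_gte(nrow(up), 50)
  rc <- count_matrix(up, ins, sub("_[0-9]+$", "", names(ins)))
  ratio <- mean(rowMeans(rc$counts[, rc$groups == "cci"]) /
                rowMeans(rc$counts[, rc$groups == "naive"]))
  expect_lt(abs(ratio - 2) / 2, 0.1)
  # no-effect design: ratio ~= 1
  d0 <- synthetic_design(n_accessible_regions = 300, frac_dar = 0.4,
                         dar_effect = 1, depth = 2e5, seed = 18L)
  tr0 <- synthetic_truth(d0, g)
  fr0 <- generate_atac_fragments(d0, tr0, g)
  ins0 <- lapply(fr0, fragments_to_insertions, chrom_lengths = g$chrom_lengths)
  rc0 <- count_matrix(tr0$regions[tr0$regions$direction == 1L, ], ins0,
                      sub("_[0-9]+$", "", names(ins0)))
  ratio0 <- mean(rowMeans(rc0$counts[, rc0$groups == "cci"]) /
                 rowMeans(rc0$counts[, rc0$groups == "naive"]))
  expect_lt(abs(ratio0 - 1), 0.1)
})

test_that("enhancer-mark coverage count is exact", {
  for (frac in c(0, 0.5, 1)) {
    d <- synthetic_design(n_accessible_regions = 100,
                          h3k4me1_cover_frac = frac, seed = 5L)
    g <- generate_genome_and_genes(d)
    tr <- synthetic_truth(d, g)
    marks <- generate_h3k4me1_regions(d, tr, g)
    # brute-force overlap count
    hit <- vapply(seq_len(nrow(tr$regions)), function(i) {
      any(marks$chrom == tr$regions$chrom[i] &
          marks$start < tr$regions$end[i] &
          marks$end > tr$regions$start[i])
    }, logical(1))
    expect_equal(sum(hit), round(frac * 100))
    if (nrow(marks) > 0)  # marks are wider than the regions they cover
      expect_true(all(marks$end - marks$start >
                      interval_width(tr$regions)[hit][seq_len(nrow(marks))] - 1))
  }
})

test_that("RNA counts have planted direction-concordant shifts", {
  # many concordant genes for a Monte-Carlo mean of the log2 ratio
  d <- synthetic_design(n_genes = 200, n_accessible_regions = 300,
                        frac_dar = 0.5, frac_concordant_genes = 1,
                        rna_log2fc = 1, rna_dispersion = 0.05, seed = 31L)
  g <- generate_genome_and_genes(d)
  tr <- synthetic_truth(d, g)
  rna <- generate_rna_counts(d, tr, g)
  expect_equal(dim(rna$counts), c(200, 6))
  expect_true(all(rna$counts >= 0))
  up <- tr$concordant_genes$gene_id[tr$concordant_genes$direction == 1]
  expect_gte(length(up), 30)
  lr <- log2(rowMeans(rna$counts[up, rna$groups == "cci"]) /
             rowMeans(rna$counts[up, rna$groups == "naive"]))
  expect_lt(abs(mean(lr) - 1), 0.3)
  # no planted genes -> no shift beyond noise
  d0 <- synthetic_design(frac_concordant_genes = 0, seed = 31L)
  tr0 <- synthetic_truth(d0, g)
  expect_equal(nrow(tr0$concordant_genes), 0)
})

test_that("tf array grids have 4 spots per protein and planted binders score", {
  ds <- default_dataset()
  spots <- ds$array_spots
  tab <- table(spots$protein_id[spots$protein_id != "T7_ctrl"])
  expect_true(all(tab == 4))
  expect_equal(sum(spots$protein_id != "T7_ctrl") / 2,
               2 * ds$design$n_proteins)
  expect_setequal(unique(spots$dye), c("Cy3", "Cy5"))
  res <- score_tf_array(spots)
  expect_identical(sort(res$hits$protein_id),
                   sort(ds$truth$array_binders$protein_id))
})

test_that("planted truth round-trips through the sidecar file", {
  ds <- default_dataset()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_planted_truth(ds$truth, tmp)
  back <- read_planted_truth(tmp)
  expect_equal(back$regions$start, ds$truth$regions$start)
  expect_equal(back$regions$direction, ds$truth$regions$direction)
  expect_equal(back$concordant_genes, ds$truth$concordant_genes,
               ignore_attr = TRUE)
  expect_equal(back$array_binders$protein_id,
               ds$truth$array_binders$protein_id)
  # full writer produces every expected file
  dir <- withr::local_tempdir()
  write_synthetic_dataset(ds, dir)
  expect_true(all(file.exists(file.path(dir,
    c("naive_1.fragments.bed", "cci_3.fragments.bed", "h3k4me1.bed",
      "genes.tsv", "rna_counts.tsv", "tf_array.tsv", "truth.tsv")))))
})
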