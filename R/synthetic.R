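# Synthetic multi-omic dataset with planted ground truth: toy genome and gene
# models, per-sample ATAC fragments with group-specific accessibility effects
# at a minority of regions, enhancer-mark regions co-localizing with them,
# RNA-seq counts with direction-concordant expression shifts, and dye-swap
# protein-microarray grids with rare strong binders.

#' Synthetic study design
#'
#' Parameters of the generated dataset. The defaults emulate the profiled
#' study design at desk scale: two groups (naive vs injured/CCI) with 3
#' biological replicates each, a minority of accessible regions carrying a
#' multiplicative group effect, enhancer-mark coverage of most accessible
#' regions, and expression changes concordant with accessibility at half of
#' the affected regions' nearest genes.
#'
#' @param genome_length Bases per chromosome.
#' @param n_chromosomes Number of chromosomes.
#' @param n_genes Number of genes.
#' @param n_accessible_regions Number of accessible (peak) regions.
#' @param frac_dar Fraction of accessible regions with a planted group effect.
#' @param dar_effect Multiplicative accessibility effect (> 0); increased
#'   regions are `dar_effect`-fold more accessible in the CCI group,
#'   decreased regions `dar_effect`-fold more accessible in the naive group.
#' @param n_samples_per_group Biological replicates per condition.
#' @param depth Fragments per sample.
#' @param h3k4me1_cover_frac Fraction of accessible regions overlapped by an
#'   enhancer-mark region (planted differential regions are covered first).
#' @param frac_concordant_genes Fraction of differential regions whose
#'   nearest gene receives a same-direction expression effect.
#' @param frip Fraction of fragments falling in accessible regions.
#' @param rna_log2fc Magnitude of the planted expression log2 fold change.
#' @param rna_mean_log,rna_mean_sdlog Log-normal parameters of baseline gene
#'   expression means.
#' @param rna_dispersion Negative-binomial dispersion of RNA counts.
#' @param n_proteins Proteins printed on each microarray.
#' @param n_binders Planted strong binders.
#' @param binder_multiplier Foreground multiplier of binder spots.
#' @param seed Integer master seed; identical seeds give identical datasets.
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(genome_length = 2.5e6,
                             n_chromosomes = 2,
                             n_genes = 200,
                             n_accessible_regions = 300,
                             frac_dar = 0.1,
                             dar_effect = 3,
                             n_samples_per_group = 3,
                             depth = 2e5,
                             h3k4me1_cover_frac = 0.8,
                             frac_concordant_genes = 0.5,
                             frip = 0.5,
                             rna_log2fc = 2,
                             rna_mean_log = log(500),
                             rna_mean_sdlog = 1,
                             rna_dispersion = 0.01,
                             n_proteins = 500,
                             n_binders = 1,
                             binder_multiplier = 10,
                             seed = 1L) {
  d <- as.list(environment())
  fracs <- c(d$frac_dar, d$h3k4me1_cover_frac, d$frac_concordant_genes, d$frip)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (d$depth <= 0 || d$n_accessible_regions <= 0 || d$n_samples_per_group <= 0)
    stop("depth and counts must be positive")
  if (d$dar_effect <= 0) stop("dar_effect must be > 0")
  d$seed <- as.integer(seed)
  structure(d, class = "synthetic_design")
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat(sprintf(paste0("synthetic_design: %d x %.3g Mb genome, %d genes, ",
                     "%d regions (%.0f%% differential, effect %gx), ",
                     "%d+%d samples, %.3g fragments/sample, seed %d\n"),
              x$n_chromosomes, x$genome_length / 1e6, x$n_genes,
              x$n_accessible_regions, 100 * x$frac_dar, x$dar_effect,
              x$n_samples_per_group, x$n_samples_per_group, x$depth, x$seed))
  invisible(x)
}

chrom_lengths_of <- function(design)
  setNames(rep(design$genome_length, design$n_chromosomes),
           paste0("chr", seq_len(design$n_chromosomes)))

#' Generate the toy genome and gene models
#'
#' Places non-overlapping genes (with 2-4 exons each) in evenly spaced slots
#' across the chromosomes, deterministic under the design seed.
#'
#' @param design A `synthetic_design`.
#' @return List: `chrom_lengths` (named vector), `genes` (gene model table
#'   with `gene_id`, `chrom`, `tss`, `tes`, `strand`), `exons` (`gene_id`,
#'   `chrom`, `start`, `end`).
#' @export
generate_genome_and_genes <- function(design) {
  cl <- chrom_lengths_of(design)
  empty_genes <- data.frame(gene_id = character(), chrom = character(),
                            tss = numeric(), tes = numeric(),
                            strand = character(), stringsAsFactors = FALSE)
  empty_exons <- data.frame(gene_id = character(), chrom = character(),
                            start = numeric(), end = numeric(),
                            stringsAsFactors = FALSE)
  if (design$n_genes == 0)
    return(list(chrom_lengths = cl, genes = empty_genes, exons = empty_exons))
  per_chrom <- diff(round(seq(0, design$n_genes,
                              length.out = design$n_chromosomes + 1)))
  max_len <- 10000
  if (any(per_chrom > 0) &&
      design$genome_length / max(per_chrom) < max_len + 2000)
    stop("genome too small to place ", design$n_genes, " genes")
  with_seed(design$seed + 11L, {
    genes <- empty_genes; exons <- empty_exons
    gid <- 0
    for (ci in seq_len(design$n_chromosomes)) {
      ng <- per_chrom[ci]
      if (ng == 0) next
      slot <- design$genome_length / ng
      for (k in seq_len(ng)) {
        gid <- gid + 1
        len <- round(runif(1, 2000, max_len))
        left <- round((k - 1) * slot + runif(1, 500, slot - len - 500))
        right <- left + len
        strand <- sample(c("+", "-"), 1)
        id <- sprintf("gene%03d", gid)
        genes <- rbind(genes, data.frame(
          gene_id = id, chrom = names(cl)[ci],
          tss = if (strand == "+") left else right - 1,
          tes = if (strand == "+") right - 1 else left,
          strand = strand, stringsAsFactors = FALSE))
        n_ex <- sample(2:4, 1)
        cuts <- sort(sample(seq(200, len - 200, by = 50), 2 * n_ex - 2))
        bounds <- c(0, cuts, len)
        for (e in seq_len(n_ex)) {
          exons <- rbind(exons, data.frame(
            gene_id = id, chrom = names(cl)[ci],
            start = left + bounds[2 * e - 1], end = left + bounds[2 * e],
            stringsAsFactors = FALSE))
        }
      }
    }
    list(chrom_lengths = cl, genes = genes, exons = exons)
  })
}

#' Plant the ground truth
#'
#' Places the accessible regions, selects which carry a group effect (and in
#' which direction), chooses the concordant nearest genes, and names the
#' microarray binders. Serialize with [write_planted_truth()].
#'
#' @param design A `synthetic_design`.
#' @param genome Output of [generate_genome_and_genes()].
#' @return A `planted_truth` list: `regions` (all accessible regions with
#'   `region_id`, `is_dar`, `direction` in -1/0/+1), `dar_regions`,
#'   `concordant_genes` (`gene_id`, `direction`), `array_binders`
#'   (`protein_id`, `multiplier`).
#' @export
synthetic_truth <- function(design, genome) {
  cl <- genome$chrom_lengths
  nreg <- design$n_accessible_regions
  per_chrom <- diff(round(seq(0, nreg, length.out = design$n_chromosomes + 1)))
  with_seed(design$seed + 23L, {
    regions <- do.call(rbind, lapply(seq_len(design$n_chromosomes), function(ci) {
      nr <- per_chrom[ci]
      if (nr == 0) return(NULL)
      slot <- cl[ci] / nr
      width <- round(runif(nr, 300, 600))
      center <- round((seq_len(nr) - 0.5) * slot + runif(nr, -slot / 8, slot / 8))
      data.frame(chrom = names(cl)[ci],
                 start = pmax(round(center - width / 2), 0),
                 end = pmin(round(center + width / 2), cl[ci]),
                 stringsAsFactors = FALSE)
    }))
    regions$region_id <- sprintf("region%03d", seq_len(nrow(regions)))
    n_dar <- round(design$frac_dar * nreg)
    dar_idx <- sort(sample.int(nreg, n_dar))
    regions$is_dar <- seq_len(nreg) %in% dar_idx
    regions$direction <- 0L
    if (n_dar > 0)   # alternate increased/decreased along the genome
      regions$direction[dar_idx] <- rep_len(c(1L, -1L), n_dar)
    # concordant genes: nearest gene of each planted region, deduplicated
    conc <- data.frame(gene_id = character(), direction = integer(),
                       stringsAsFactors = FALSE)
    if (n_dar > 0 && nrow(genome$genes) > 0) {
      nn <- nearest_tss(regions[regions$is_dar, , drop = FALSE], genome$genes)
      cand <- data.frame(gene_id = nn$gene_id,
                         direction = regions$direction[regions$is_dar],
                         stringsAsFactors = FALSE)
      cand <- cand[!is.na(cand$gene_id) & !duplicated(cand$gene_id), , drop = FALSE]
      n_conc <- round(design$frac_concordant_genes * nrow(cand))
      if (n_conc > 0) {
        conc <- cand[sort(sample.int(nrow(cand), n_conc)), , drop = FALSE]
        rownames(conc) <- NULL
      }
    }
    binders <- data.frame(protein_id = character(), multiplier = numeric(),
                          stringsAsFactors = FALSE)
    if (design$n_binders > 0) {
      ids <- sprintf("TF%03d", sort(sample.int(design$n_proteins,
                                               design$n_binders)))
      binders <- data.frame(protein_id = ids,
                            multiplier = design$binder_multiplier,
                            stringsAsFactors = FALSE)
    }
    structure(list(regions = regions,
                   dar_regions = regions[regions$is_dar, , drop = FALSE],
                   concordant_genes = conc, array_binders = binders),
              class = "planted_truth")
  })
}

#' Generate per-sample ATAC fragments
#'
#' Each sample's fragments are a mixture of uniform background and
#' peak-concentrated fragments whose centres are Gaussian around accessible
#' region centres (sd = width / 4). Planted regions have group mean rates
#' differing by `dar_effect`. Fragment lengths follow a nucleosome-free
#' (~80 bp) / mono-nucleosome (~200 bp) mixture; exactly `depth` fragments
#' per sample.
#'
#' @param design A `synthetic_design`.
#' @param truth A `planted_truth`.
#' @param genome Output of [generate_genome_and_genes()].
#' @return Named list of fragment interval tables (`naive_1`, ..., `cci_1`,
#'   ...), each with `name`, `score`, `strand` columns (BED6-ready).
#' @export
generate_atac_fragments <- function(design, truth, genome) {
  cl <- genome$chrom_lengths
  reg <- truth$regions
  if (design$depth < nrow(reg))
    warning("depth is below the number of accessible regions")
  samples <- c(paste0("naive_", seq_len(design$n_samples_per_group)),
               paste0("cci_", seq_len(design$n_samples_per_group)))
  out <- lapply(seq_along(samples), function(si) {
    grp <- if (si <= design$n_samples_per_group) "naive" else "cci"
    with_seed(design$seed + 100L + si, {
      w <- rep(1, nrow(reg))
      if (grp == "cci") w[reg$direction == 1L] <- design$dar_effect
      if (grp == "naive") w[reg$direction == -1L] <- design$dar_effect
      probs <- c((1 - design$frip), design$frip * w / sum(w))
      alloc <- as.vector(rmultinom(1, design$depth, probs))
      # background: uniform over the genome
      n_bg <- alloc[1]
      bg_chrom <- sample(names(cl), n_bg, replace = TRUE,
                         prob = cl / sum(cl))
      centers <- data.frame(chrom = bg_chrom,
                            center = floor(runif(n_bg) * cl[bg_chrom]),
                            stringsAsFactors = FALSE)
      # peaks: Gaussian around region centres
      for (r in which(alloc[-1] > 0)) {
        n_r <- alloc[r + 1]
        mid <- (reg$start[r] + reg$end[r]) / 2
        sdr <- (reg$end[r] - reg$start[r]) / 4
        centers <- rbind(centers, data.frame(
          chrom = reg$chrom[r],
          center = round(rnorm(n_r, mid, sdr)), stringsAsFactors = FALSE))
      }
      len <- ifelse(runif(nrow(centers)) < 0.6,
                    rnorm(nrow(centers), 80, 15),
                    rnorm(nrow(centers), 200, 25))
      len <- pmax(round(len), 30)
      start <- round(centers$center - len / 2)
      start <- pmax(start, 0)
      end <- pmin(start + len, cl[centers$chrom])
      start <- pmax(pmin(start, end - 30), 0)
      frag <- data.frame(chrom = centers$chrom, start = start,
                         end = unname(end),
                         name = sprintf("frag%d", seq_len(nrow(centers))),
                         score = 0L,
                         strand = sample(c("+", "-"), nrow(centers),
                                         replace = TRUE),
                         stringsAsFactors = FALSE)
      frag <- frag[order(frag$chrom, frag$start), , drop = FALSE]
      rownames(frag) <- NULL
      frag
    })
  })
  names(out) <- samples
  out
}

#' Generate enhancer-mark (H3K4me1-like) regions
#'
#' Emits one mark region per covered accessible region, widened by `pad`
#' bases on each side so marks are broader than the accessibility peaks.
#' Exactly `round(h3k4me1_cover_frac * n_accessible_regions)` accessible
#' regions end up overlapped; planted differential regions are covered first
#' (their enhancer identity is the premise of the design).
#'
#' @param design A `synthetic_design`.
#' @param truth A `planted_truth`.
#' @param genome Output of [generate_genome_and_genes()].
#' @param pad Widening in bases on each side.
#' @return Interval table of mark regions.
#' @export
generate_h3k4me1_regions <- function(design, truth, genome, pad = 300) {
  reg <- truth$regions
  n_cover <- round(design$h3k4me1_cover_frac * nrow(reg))
  if (n_cover == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  with_seed(design$seed + 37L, {
    dar <- which(reg$is_dar)
    other <- setdiff(seq_len(nrow(reg)), dar)
    covered <- if (n_cover <= length(dar)) sort(sample(dar, n_cover))
    else sort(c(dar, sample(other, n_cover - length(dar))))
    marks <- data.frame(
      chrom = reg$chrom[covered],
      start = pmax(reg$start[covered] - pad, 0),
      end = pmin(reg$end[covered] + pad,
                 genome$chrom_lengths[reg$chrom[covered]]),
      stringsAsFactors = FALSE)
    rownames(marks) <- NULL
    # the padded marks must not graze uncovered regions
    ov <- overlap_query(reg, marks)
    stopifnot(identical(sort(unique(ov$pairs$a_idx)), covered))
    marks
  })
}

#' Generate RNA-seq counts
#'
#' Gene-level negative-binomial counts for both groups; planted concordant
#' genes receive a group log2 mean shift of `rna_log2fc` with the sign of
#' their region's accessibility direction.
#'
#' @param design A `synthetic_design`.
#' @param truth A `planted_truth`.
#' @param genome Output of [generate_genome_and_genes()].
#' @return List: `counts` (genes x samples integer matrix), `groups`.
#' @export
generate_rna_counts <- function(design, truth, genome) {
  genes <- genome$genes
  samples <- c(paste0("naive_", seq_len(design$n_samples_per_group)),
               paste0("cci_", seq_len(design$n_samples_per_group)))
  groups <- rep(c("naive", "cci"), each = design$n_samples_per_group)
  with_seed(design$seed + 53L, {
    base <- rlnorm(nrow(genes), design$rna_mean_log, design$rna_mean_sdlog)
    shift <- rep(0, nrow(genes))
    hit <- match(truth$concordant_genes$gene_id, genes$gene_id)
    shift[hit[!is.na(hit)]] <-
      design$rna_log2fc * truth$concordant_genes$direction[!is.na(hit)]
    mu <- cbind(matrix(base, nrow(genes), design$n_samples_per_group),
                matrix(base * 2^shift, nrow(genes), design$n_samples_per_group))
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / design$rna_dispersion),
                     nrow = nrow(genes),
                     dimnames = list(genes$gene_id, samples))
    list(counts = counts, groups = setNames(groups, samples))
  })
}

#' Generate a dye-swap pair of protein-microarray grids
#'
#' Each protein occupies 2 spots per array on 2 arrays (Cy3 / Cy5 probes);
#' leftover grid positions are filled with `T7_ctrl` control probes.
#' Foreground and background medians are log-normal; binder spots'
#' foreground is multiplied by the planted multiplier on all 4 spots.
#'
#' @param design A `synthetic_design`.
#' @param truth A `planted_truth`.
#' @return Spot data.frame for both arrays (see [read_array_grid()]).
#' @export
generate_tf_array <- function(design, truth) {
  np <- design$n_proteins
  stopifnot(np >= 1)
  ncol_grid <- 32
  n_spots <- 2 * np
  nrow_grid <- ceiling(n_spots / ncol_grid)
  total <- nrow_grid * ncol_grid
  proteins <- sprintf("TF%03d", seq_len(np))
  mult <- setNames(rep(1, np), proteins)
  if (nrow(truth$array_binders) > 0)
    mult[truth$array_binders$protein_id] <- truth$array_binders$multiplier
  with_seed(design$seed + 71L, {
    out <- do.call(rbind, lapply(1:2, function(ai) {
      ids <- c(rep(proteins, each = 2), rep("T7_ctrl", total - n_spots))
      repl <- c(rep(1:2, np), rep(1L, total - n_spots))
      ord <- sample.int(total)
      pos <- cbind(row = (seq_len(total) - 1) %/% ncol_grid + 1,
                   col = (seq_len(total) - 1) %% ncol_grid + 1)
      B <- rlnorm(total, log(400), 0.3)
      f_mult <- ifelse(ids[ord] == "T7_ctrl", 1, mult[ids[ord]])
      F <- B * exp(rnorm(total, 0, 0.15)) * f_mult
      data.frame(array_id = sprintf("array%d", ai),
                 row = pos[, "row"], col = pos[, "col"],
                 protein_id = ids[ord], replicate = repl[ord],
                 dye = c("Cy3", "Cy5")[ai],
                 F = round(F, 2), B = round(B, 2), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate random chromosome sequences for the toy genome
#'
#' Independent bases at the given GC content; only needed by the motif
#' module.
#'
#' @param chrom_lengths Named chromosome lengths.
#' @param gc GC content.
#' @param seed Seed.
#' @return Named character vector of sequences.
#' @export
generate_genome_sequence <- function(chrom_lengths, gc = 0.42, seed = 1L) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    vapply(chrom_lengths, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      character(1))
  })
}

#' Generate the complete synthetic dataset
#'
#' Runs every generator under the design's master seed.
#'
#' @param design A `synthetic_design`.
#' @return List: `design`, `genome`, `truth`, `fragments`, `marks`, `rna`,
#'   `array_spots`, and `groups` (per ATAC sample).
#' @export
synthetic_dataset <- function(design = synthetic_design()) {
  genome <- generate_genome_and_genes(design)
  truth <- synthetic_truth(design, genome)
  fragments <- generate_atac_fragments(design, truth, genome)
  marks <- generate_h3k4me1_regions(design, truth, genome)
  rna <- generate_rna_counts(design, truth, genome)
  spots <- generate_tf_array(design, truth)
  groups <- setNames(sub("_[0-9]+$", "", names(fragments)), names(fragments))
  list(design = design, genome = genome, truth = truth, fragments = fragments,
       marks = marks, rna = rna, array_spots = spots, groups = groups)
}

#' Write the planted truth sidecar
#'
#' One TSV holding the planted regions, concordant genes and array binders,
#' so downstream checks never re-derive the truth.
#'
#' @param truth A `planted_truth`.
#' @param path Output path.
#' @export
write_planted_truth <- function(truth, path) {
  reg <- truth$regions
  rows <- data.frame(record = "region", id = reg$region_id, chrom = reg$chrom,
                     start = reg$start, end = reg$end,
                     direction = reg$direction, multiplier = NA_real_,
                     stringsAsFactors = FALSE)
  if (nrow(truth$concordant_genes) > 0)
    rows <- rbind(rows, data.frame(
      record = "concordant_gene", id = truth$concordant_genes$gene_id,
      chrom = NA, start = NA, end = NA,
      direction = truth$concordant_genes$direction, multiplier = NA_real_))
  if (nrow(truth$array_binders) > 0)
    rows <- rbind(rows, data.frame(
      record = "array_binder", id = truth$array_binders$protein_id,
      chrom = NA, start = NA, end = NA, direction = NA,
      multiplier = truth$array_binders$multiplier))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a planted-truth sidecar
#' @param path TSV written by [write_planted_truth()].
#' @return A `planted_truth` list.
#' @export
read_planted_truth <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  reg <- d[d$record == "region", , drop = FALSE]
  regions <- data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                        region_id = reg$id, is_dar = reg$direction != 0,
                        direction = as.integer(reg$direction),
                        stringsAsFactors = FALSE)
  cg <- d[d$record == "concordant_gene", , drop = FALSE]
  ab <- d[d$record == "array_binder", , drop = FALSE]
  rownames(regions) <- NULL
  structure(list(
    regions = regions,
    dar_regions = regions[regions$is_dar, , drop = FALSE],
    concordant_genes = data.frame(gene_id = cg$id,
                                  direction = as.integer(cg$direction),
                                  stringsAsFactors = FALSE),
    array_binders = data.frame(protein_id = ab$id,
                               multiplier = ab$multiplier,
                               stringsAsFactors = FALSE)),
    class = "planted_truth")
}

#' Write every synthetic input to a directory
#'
#' Fragments as per-sample BED6, marks as BED3, gene models and RNA counts as
#' TSV, arrays as TSV, and the truth sidecar.
#'
#' @param ds Output of [synthetic_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(ds$fragments))
    write_bed(ds$fragments[[s]], file.path(dir, paste0(s, ".fragments.bed")))
  write_bed(ds$marks, file.path(dir, "h3k4me1.bed"))
  write_gene_models(ds$genome$genes, file.path(dir, "genes.tsv"))
  write_count_matrix(ds$rna$counts, file.path(dir, "rna_counts.tsv"),
                     id_name = "gene_id")
  write_array_grid(ds$array_spots, file.path(dir, "tf_array.tsv"))
  write_planted_truth(ds$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
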