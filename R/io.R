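# Readers/writers for the plain-text genomics formats the pipeline touches.
# All files are tab-separated without headers unless noted; coordinates on
# disk follow each format's own convention (BED family: 0-based half-open).

#' Read a BED file
#'
#' Accepts BED3 through BED6; extra columns beyond the sixth are ignored.
#'
#' @param path File path.
#' @return Interval table with `name`, `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE, quote = "")
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  if (ncol(d) >= 5) names(d)[5] <- "score"
  if (ncol(d) >= 6) names(d)[6] <- "strand"
  validate_intervals(d)
  d[, seq_len(min(ncol(d), 6)), drop = FALSE]
}

#' Write a BED file
#'
#' @param intervals Interval table; `name`, `score`, `strand` columns are
#'   written when present (BED6), otherwise BED3.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  validate_intervals(intervals)
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(intervals)))
    cols <- c(cols, "name", "score", "strand")
  write.table(format(intervals[, cols, drop = FALSE], scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak file
#'
#' The 10-column ENCODE narrowPeak format: BED6 plus signalValue, pValue
#' (-log10), qValue (-log10) and the summit offset from `start`.
#'
#' @param path File path.
#' @return data.frame of peak records.
#' @export
read_narrowpeak <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 10) stop("narrowPeak requires 10 columns, got ", ncol(d))
  names(d) <- c("chrom", "start", "end", "name", "score", "strand",
                "signal", "pvalue", "qvalue", "summit_offset")
  validate_intervals(d)
  if (any(d$summit_offset < 0 | d$summit_offset >= d$end - d$start))
    stop("summit offset outside peak")
  d
}

#' Write a narrowPeak file
#' @param peaks data.frame as returned by [call_peaks_simple()].
#' @param path Output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "summit_offset")
  stopifnot(all(cols %in% names(peaks)))
  write.table(format(peaks[, cols], scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a bedGraph track
#'
#' Emits one line per bin (`chrom start end value`), skipping zero bins to
#' keep files small; the text counterpart of the bigWig tracks genome
#' browsers display.
#'
#' @param track A `binned_track` (see [binned_coverage()]).
#' @param path Output path.
#' @param keep_zero Write zero-valued bins too (default drops them).
#' @export
write_bedgraph <- function(track, path, keep_zero = FALSE) {
  stopifnot(inherits(track, "binned_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    start <- (seq_along(v) - 1) * track$bin_width
    end <- pmin(start + track$bin_width, track$chrom_lengths[[ch]])
    keep <- if (keep_zero) rep(TRUE, length(v)) else v != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ch, start[keep], end[keep], v[keep]), con)
  }
  invisible(path)
}

#' Read a gene model table
#'
#' Five tab-separated columns with header: `gene_id`, `chrom`, `tss`, `tes`,
#' `strand`. TSS/TES are 0-based positions (the TSS of a minus-strand gene is
#' numerically larger than its TES).
#'
#' @param path File path.
#' @return Gene model data.frame.
#' @export
read_gene_models <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "tes", "strand")
  if (!all(need %in% names(d))) stop("gene model table needs columns: ",
                                     paste(need, collapse = ", "))
  d
}

#' Write a gene model table
#' @param genes Gene model data.frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  write.table(genes[, c("gene_id", "chrom", "tss", "tes", "strand")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from a GTF file
#'
#' Uses rtracklayer to import the GTF, keeps `gene` features (or derives gene
#' spans from transcripts when absent), and converts them to the package's
#' TSS/TES table.
#'
#' @param path GTF file path.
#' @return Gene model data.frame as from [read_gene_models()].
#' @export
read_gene_models_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- as.data.frame(gr)
  if ("type" %in% names(meta) && any(meta$type == "gene"))
    meta <- meta[meta$type == "gene", , drop = FALSE]
  if (!"gene_id" %in% names(meta)) stop("GTF lacks gene_id attribute")
  meta <- meta[!duplicated(meta$gene_id), , drop = FALSE]
  start0 <- meta$start - 1  # GTF is 1-based inclusive
  data.frame(gene_id = meta$gene_id,
             chrom = as.character(meta$seqnames),
             tss = ifelse(meta$strand == "-", meta$end - 1, start0),
             tes = ifelse(meta$strand == "-", start0, meta$end - 1),
             strand = as.character(meta$strand),
             stringsAsFactors = FALSE)
}

#' Read a count matrix TSV
#'
#' First column is the feature identifier, remaining columns one sample each
#' (header row with sample names).
#'
#' @param path File path.
#' @return Integer matrix with feature rownames.
#' @export
read_count_matrix <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write a count matrix TSV
#' @param mat Matrix with feature rownames.
#' @param path Output path.
#' @param id_name Header for the identifier column.
#' @export
write_count_matrix <- function(mat, path, id_name = "feature_id") {
  d <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(d)[1] <- id_name
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read position weight matrices in JASPAR text format
#'
#' Parses the JASPAR flat format: a `>ID name` header followed by four rows of
#' per-position counts, with or without the `A [ ... ]` row labels/brackets.
#'
#' @param path File path.
#' @return Named list of PWM objects (see [pwm_from_counts()]).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) stop("no JASPAR records in ", path)
  out <- list()
  for (k in seq_along(heads)) {
    i <- heads[k]
    j <- if (k < length(heads)) heads[k + 1] - 1 else length(lines)
    block <- lines[(i + 1):j]
    if (length(block) < 4) stop("JASPAR record with fewer than 4 matrix rows")
    hdr <- strsplit(sub("^>", "", lines[i]), "[[:space:]]+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) paste(hdr[-1], collapse = " ") else id
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]", "", trimws(l))
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) stop("ragged JASPAR matrix for ", id)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    out[[id]] <- pwm_from_counts(counts, motif_id = id, name = name)
  }
  out
}

#' Write PWMs in JASPAR text format
#' @param pwms Named list of PWM objects.
#' @param path Output path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$motif_id, p$name), con)
    cn <- p$counts
    for (b in c("A", "C", "G", "T"))
      writeLines(sprintf("%s [ %s ]", b, paste(format(cn[b, ]), collapse = " ")), con)
  }
  invisible(path)
}

#' Read chromosome sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write chromosome sequences to a FASTA file
#'
#' @param genome Named character vector (or `DNAStringSet`) of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' Read a microarray spot grid
#'
#' Tab-separated with header: `array_id`, `row`, `col`, `protein_id`,
#' `replicate`, `dye`, `F`, `B` (foreground/background median intensities).
#'
#' @param path File path.
#' @return Spot data.frame.
#' @export
read_array_grid <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("array_id", "row", "col", "protein_id", "replicate", "dye", "F", "B")
  if (!all(need %in% names(d))) stop("array grid needs columns: ",
                                     paste(need, collapse = ", "))
  d
}

#' Write a microarray spot grid
#' @param spots Spot data.frame.
#' @param path Output path.
#' @export
write_array_grid <- function(spots, path) {
  write.table(spots, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
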