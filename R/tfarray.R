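# Protein-microarray binding scores: F/B raw intensity, neighbouring-probe
# local normalization, trimmed noise model, Z-scores, all-4-spots hit rule.

#' Raw binding intensity
#'
#' The raw intensity of a spot is the ratio of foreground to background median
#' intensities, `F / B`, with the background floored to avoid division
#' blow-ups on dark spots. Spots with missing foreground are flagged invalid.
#'
#' @param spots Spot data.frame (see [read_array_grid()]).
#' @param b_floor Background intensity floor.
#' @return `spots` with columns `raw` and logical `valid`.
#' @export
raw_intensity <- function(spots, b_floor = 1) {
  stopifnot(all(c("F", "B") %in% names(spots)), b_floor > 0)
  spots$valid <- !is.na(spots$F) & !is.na(spots$B) & spots$F >= 0
  spots$raw <- ifelse(spots$valid, spots$F / pmax(spots$B, b_floor), NA_real_)
  spots
}

#' Local normalization against neighbouring probes
#'
#' Divides each spot's raw intensity by the median raw intensity of its
#' neighbouring probes on the printed grid (8-connected ring by default,
#' excluding the spot itself); edge and corner spots use their available
#' neighbours (5 or 3 at radius 1). This removes the spatial intensity
#' gradients slide scanners produce. Spots whose neighbourhood median is not
#' positive are flagged invalid.
#'
#' @param spots Spot data.frame for a single array, with `raw` (see
#'   [raw_intensity()]).
#' @param radius Ring radius in grid units (1 = 8-neighbourhood).
#' @return `spots` with column `local_norm` (valid flag updated).
#' @export
local_normalize <- function(spots, radius = 1) {
  stopifnot(all(c("row", "col", "raw") %in% names(spots)), radius >= 1)
  if (length(unique(spots$array_id)) > 1)
    stop("local_normalize operates on a single array")
  nr <- max(spots$row); nc <- max(spots$col)
  if (nr < 3 || nc < 3) stop("grid must be at least 3 x 3")
  grid <- matrix(NA_real_, nr, nc)
  grid[cbind(spots$row, spots$col)] <- spots$raw
  ln <- numeric(nrow(spots))
  for (k in seq_len(nrow(spots))) {
    i <- spots$row[k]; j <- spots$col[k]
    ri <- max(1, i - radius):min(nr, i + radius)
    rj <- max(1, j - radius):min(nc, j + radius)
    nb <- grid[ri, rj]
    self <- which(ri == i) + (which(rj == j) - 1) * length(ri)
    med <- median(nb[-self], na.rm = TRUE)
    ln[k] <- if (is.na(med) || med <= 0 || is.na(spots$raw[k])) NA_real_
             else spots$raw[k] / med
  }
  spots$local_norm <- ln
  spots$valid <- spots$valid & !is.na(ln)
  spots
}

#' Fit the array noise model
#'
#' The noise distribution is taken as the locally normalized intensities of
#' all valid (non-control) spots after discarding the top `trim_fraction` —
#' true binders are rare, bright outliers, and trimming keeps them from
#' inflating the noise spread. Returns the trimmed mean and standard
#' deviation used for Z-scores.
#'
#' @param local_norm Numeric vector of locally normalized intensities.
#' @param trim_fraction Fraction of the highest values to discard.
#' @return List (`array_noise_model`): `noise_mean`, `noise_sd`,
#'   `n_spots_used`, `trim_fraction`.
#' @export
fit_noise_model <- function(local_norm, trim_fraction = 0.05) {
  stopifnot(trim_fraction >= 0, trim_fraction < 1)
  x <- local_norm[!is.na(local_norm)]
  if (length(x) < 30) stop("noise model requires at least 30 valid spots")
  n_drop <- floor(trim_fraction * length(x))
  if (n_drop > 0) x <- sort(x)[seq_len(length(x) - n_drop)]
  m <- mean(x); s <- sd(x)
  if (!is.finite(s) || s <= 0)
    stop("degenerate noise distribution (zero spread)")
  structure(list(noise_mean = m, noise_sd = s, n_spots_used = length(x),
                 trim_fraction = trim_fraction),
            class = "array_noise_model")
}

#' @export
print.array_noise_model <- function(x, ...) {
  cat(sprintf("array noise model: mean %.4f, sd %.4f (n = %d, trim %.0f%%)\n",
              x$noise_mean, x$noise_sd, x$n_spots_used, 100 * x$trim_fraction))
  invisible(x)
}

is_control_spot <- function(spots) startsWith(spots$protein_id, "T7")

#' Score a dye-swap pair of arrays
#'
#' Full scoring pipeline for one binding assay: raw F/B intensity, local
#' normalization and a trimmed noise model per array (controls excluded from
#' the model), Z-scores `(R' - mean) / sd`, and hit calling.
#'
#' @param spots Spot data.frame covering the dye-swap pair (two `array_id`s).
#' @param z_min Z-score every spot must exceed (strictly) for a hit.
#' @param trim_fraction Noise-model trim fraction.
#' @param b_floor Background floor for raw intensity.
#' @param radius Local-normalization ring radius.
#' @return List: `spots` (with `raw`, `local_norm`, `z`), `noise_models`
#'   (per array), `hits` (see [call_hits()]).
#' @export
score_tf_array <- function(spots, z_min = 3.0, trim_fraction = 0.05,
                           b_floor = 1, radius = 1) {
  models <- list()
  scored <- do.call(rbind, lapply(split(spots, spots$array_id), function(a) {
    a <- raw_intensity(a, b_floor = b_floor)
    a <- local_normalize(a, radius = radius)
    nm <- fit_noise_model(a$local_norm[a$valid & !is_control_spot(a)],
                          trim_fraction = trim_fraction)
    models[[as.character(a$array_id[1])]] <<- nm
    a$z <- (a$local_norm - nm$noise_mean) / nm$noise_sd
    a
  }))
  rownames(scored) <- NULL
  list(spots = scored, noise_models = models,
       hits = call_hits(scored, z_min = z_min))
}

#' All-4-spots hit rule
#'
#' Each protein is printed twice per array and assayed on a dye-swap pair, so
#' it owns exactly 4 spots. A protein is a positive hit only when all 4 spots
#' have Z strictly greater than `z_min`. Control probes are never callable;
#' proteins without exactly 4 valid spots are excluded and reported.
#'
#' @param spots Scored spot data.frame with `z` and `valid`.
#' @param z_min Strict Z threshold.
#' @return data.frame of hit proteins (`protein_id`, `min_z`, the 4 z-values
#'   as `z1..z4`), with attribute `excluded` (protein ids lacking 4 valid
#'   spots).
#' @export
call_hits <- function(spots, z_min = 3.0) {
  stopifnot("z" %in% names(spots))
  spots <- spots[!is_control_spot(spots), , drop = FALSE]
  excluded <- character(0)
  rows <- list()
  for (pid in unique(spots$protein_id)) {
    sp <- spots[spots$protein_id == pid & spots$valid, , drop = FALSE]
    if (nrow(sp) != 4 || length(unique(sp$array_id)) != 2) {
      excluded <- c(excluded, pid)
      next
    }
    if (all(sp$z > z_min)) {
      z <- sort(sp$z, decreasing = TRUE)
      rows[[pid]] <- data.frame(protein_id = pid, min_z = min(sp$z),
                                z1 = z[1], z2 = z[2], z3 = z[3], z4 = z[4],
                                stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), min_z = numeric(), z1 = numeric(),
               z2 = numeric(), z3 = numeric(), z4 = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
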