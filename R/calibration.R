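#' Classify transcription factors by expression
#'
#' Expression classes used by the footprint-quality calibration:
#' highly expressed TFs (RPKM > 10 in every sample) proxy true-positive
#' binding sites, undetectable TFs (RPKM = 0 in every sample) proxy false
#' positives, and tissue-expressed TFs (RPKM >= 1 in at least one sample)
#' are used for enrichment stratification. The classes need not partition
#' the TF universe.
#'
#' @param expr Numeric matrix of RPKM values, TFs in rows (rownames = TF
#'   ids), samples in columns.
#' @return List of character vectors `highly_expressed`, `undetectable`,
#'   `brain_expressed`.
#' @export
classify_tfs <- function(expr) {
  stopifnot(is.matrix(expr), nrow(expr) > 0, !is.null(rownames(expr)))
  if (any(expr < 0)) stop("RPKM values must be non-negative")
  mins <- apply(expr, 1, min)
  maxs <- apply(expr, 1, max)
  list(
    highly_expressed = rownames(expr)[mins > 10],
    undetectable = rownames(expr)[maxs == 0],
    brain_expressed = rownames(expr)[maxs >= 1]
  )
}

#' Central conservation of a motif relative to its flanks
#'
#' Mean conservation over the motif minus the mean over its two abutting
#' flanks of `flank_bp` each; track values are treated as already
#' log-scaled. Functional motif occurrences display elevated central
#' conservation, so a positive difference (> 0.1 by default downstream) is
#' the true-positive proxy.
#'
#' @param motif A single-row [interval_set()] (or a list-like row).
#' @param track Conservation [scored_track()].
#' @param flank_bp Flank width (default 50 bp).
#' @return Numeric difference, or `NA` with a warning when a flank does not
#'   fit within the chromosome.
#' @export
delta_log_conservation <- function(motif, track, flank_bp = 50) {
  if (is.data.frame(motif)) {
    stopifnot(nrow(motif) == 1)
    chrom <- motif$chrom; start <- motif$start; end <- motif$end
  } else {
    chrom <- motif[["chrom"]]; start <- motif[["start"]]; end <- motif[["end"]]
  }
  if (end <= start) stop("zero-length motif")
  chrom_len <- length(track[[chrom]])
  if (start - flank_bp < 0 || end + flank_bp > chrom_len) {
    warning(sprintf("motif at %s:%d-%d skipped: flanks exceed chromosome",
                    chrom, start, end))
    return(NA_real_)
  }
  motif_mean <- mean(track_values(track, chrom, start, end))
  flank <- c(track_values(track, chrom, start - flank_bp, start),
             track_values(track, chrom, end, end + flank_bp))
  motif_mean - mean(flank)
}

# Vectorised delta-log conservation over an interval set (NA where flanks
# do not fit; no warning spam).
delta_log_all <- function(motifs, track, flank_bp = 50) {
  n <- nrow(motifs)
  out <- rep(NA_real_, n)
  lens <- track_chrom_lengths(track)
  for (i in seq_len(n)) {
    ch <- motifs$chrom[i]
    if (is.na(lens[ch])) next
    if (motifs$start[i] - flank_bp < 0 || motifs$end[i] + flank_bp > lens[ch]) next
    out[i] <- suppressWarnings(
      delta_log_conservation(motifs[i, , drop = FALSE], track, flank_bp)
    )
  }
  out
}

#' True-positive to false-positive footprint ratio
#'
#' Density-normalised ratio of footprint overlap with conserved
#' expressed-TF motifs against undetectable-TF motifs:
#' numerator is the fraction of footprints overlapping at least one
#' highly-expressed-TF motif with central conservation
#' (`delta_log_conservation > delta_threshold`), divided by the total base
#' pairs of the highly-expressed motif track; denominator is the fraction
#' overlapping any undetectable-TF motif divided by that track's base
#' pairs. The conservation gate applies only to the numerator.
#'
#' @param fp Footprint [interval_set()].
#' @param motifs Motif occurrence [interval_set()]; the TF id is taken from
#'   a `tf_id` column when present, else from `name`.
#' @param hi,und Character vectors of highly-expressed / undetectable TF
#'   ids (from [classify_tfs()]).
#' @param track Conservation [scored_track()].
#' @param delta_threshold Central-conservation gate (default 0.1).
#' @param flank_bp Flank width for the gate (default 50 bp).
#' @return The ratio; `Inf` when no footprint overlaps any
#'   undetectable-TF motif.
#' @export
tp_fp_ratio <- function(fp, motifs, hi, und, track, delta_threshold = 0.1,
                        flank_bp = 50) {
  fp <- as_interval_set(fp)
  motifs <- as_interval_set(motifs)
  tf <- motif_tf_ids(motifs)
  hi_m <- motifs[tf %in% hi, , drop = FALSE]
  und_m <- motifs[tf %in% und, , drop = FALSE]
  hi_bp <- interval_bp(hi_m)
  und_bp <- interval_bp(und_m)
  if (und_bp == 0) stop("undetectable-TF motif track is empty")
  if (hi_bp == 0) stop("highly-expressed-TF motif track is empty")
  if (nrow(fp) == 0) stop("no footprints")
  delta <- delta_log_all(hi_m, track, flank_bp)
  cons_hi <- hi_m[!is.na(delta) & delta > delta_threshold, , drop = FALSE]
  frac_hi <- mean(intersect_any(fp, cons_hi))
  frac_und <- mean(intersect_any(fp, und_m))
  if (frac_und == 0) return(Inf)
  (frac_hi / hi_bp) / (frac_und / und_bp)
}

motif_tf_ids <- function(motifs) {
  if (!is.null(motifs$tf_id)) motifs$tf_id else motifs$name
}

#' Select a footprint score threshold by TP:FP calibration
#'
#' Evaluates [tp_fp_ratio()] on the footprints surviving each score centile
#' of `centile_grid` and picks the smallest centile whose ratio reaches
#' `target_ratio`. The full calibration curve is returned for reporting;
#' footprint counts along it are non-increasing.
#'
#' @inheritParams tp_fp_ratio
#' @param target_ratio Required TP:FP ratio (default 2).
#' @param centile_grid Ascending centiles (default `seq(0, 95, 5)`).
#' @return List with `chosen_centile` (`NA` with a warning when no centile
#'   reaches the target) and `curve`, a `data.frame` with columns
#'   `centile`, `n_footprints`, `hi_density`, `und_density`, `ratio`.
#' @export
calibrate_threshold <- function(fp, motifs, hi, und, track, target_ratio = 2,
                                centile_grid = seq(0, 95, 5),
                                delta_threshold = 0.1, flank_bp = 50) {
  stopifnot(!is.unsorted(centile_grid))
  fp <- as_interval_set(fp)
  if (anyNA(fp$score)) stop("all footprints must carry scores")
  motifs <- as_interval_set(motifs)
  tf <- motif_tf_ids(motifs)
  hi_m <- motifs[tf %in% hi, , drop = FALSE]
  und_m <- motifs[tf %in% und, , drop = FALSE]
  hi_bp <- interval_bp(hi_m)
  und_bp <- interval_bp(und_m)
  if (und_bp == 0) stop("undetectable-TF motif track is empty")
  if (hi_bp == 0) stop("highly-expressed-TF motif track is empty")
  delta <- delta_log_all(hi_m, track, flank_bp)
  cons_hi <- hi_m[!is.na(delta) & delta > delta_threshold, , drop = FALSE]
  hit_hi <- intersect_any(fp, cons_hi)
  hit_und <- intersect_any(fp, und_m)
  curve <- data.frame(centile = centile_grid, n_footprints = NA_real_,
                      hi_density = NA_real_, und_density = NA_real_,
                      ratio = NA_real_)
  for (i in seq_along(centile_grid)) {
    cutoff <- stats::quantile(fp$score, centile_grid[i] / 100, type = 1,
                              names = FALSE)
    pass <- fp$score >= cutoff
    n <- sum(pass)
    curve$n_footprints[i] <- n
    if (n == 0) next
    hi_d <- mean(hit_hi[pass]) / hi_bp
    und_d <- mean(hit_und[pass]) / und_bp
    curve$hi_density[i] <- hi_d
    curve$und_density[i] <- und_d
    curve$ratio[i] <- if (und_d == 0) {
      if (hi_d > 0) Inf else NA_real_
    } else hi_d / und_d
  }
  ok <- which(!is.na(curve$ratio) & curve$ratio >= target_ratio)
  chosen <- if (length(ok) > 0) centile_grid[min(ok)] else NA_real_
  if (is.na(chosen)) {
    warning("no centile reaches the target TP:FP ratio")
  }
  list(chosen_centile = chosen, curve = curve)
}
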