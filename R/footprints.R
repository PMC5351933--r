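#' Remove footprints overlapping a blacklist
#'
#' Any footprint sharing at least one base pair with a blacklisted region is
#' dropped, mirroring the removal of anomalous-signal regions before
#' analysis.
#'
#' @param fp Footprint [interval_set()].
#' @param blacklist Blacklist [interval_set()].
#' @return The retained footprints.
#' @export
filter_blacklist <- function(fp, blacklist) {
  fp <- as_interval_set(fp)
  if (nrow(fp) == 0 || nrow(blacklist) == 0) return(fp)
  out <- fp[!intersect_any(fp, blacklist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict footprints to named autosomes
#'
#' @param fp Footprint [interval_set()].
#' @param autosome_names Character vector of chromosomes to keep.
#' @return The retained footprints.
#' @export
filter_autosomes <- function(fp, autosome_names) {
  fp <- as_interval_set(fp)
  out <- fp[fp$chrom %in% autosome_names, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep footprints within a width range
#'
#' @param fp Footprint [interval_set()].
#' @param min_bp,max_bp Inclusive width bounds (defaults 11 and 22 bp, the
#'   narrow footprint setting).
#' @return The retained footprints.
#' @export
filter_width <- function(fp, min_bp = 11, max_bp = 22) {
  stopifnot(min_bp <= max_bp)
  fp <- as_interval_set(fp)
  w <- fp$end - fp$start
  out <- fp[w >= min_bp & w <= max_bp, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter footprints whose local DNase cut profile is dominated by a spike
#'
#' Sequencing or alignment artefacts concentrate cut signal on a single
#' position. For each footprint the cut-count window centre +/-
#' `half_window_bp` (truncated at chromosome ends) is inspected: if the
#' largest single-position value exceeds `skew_threshold` of the window
#' total, the footprint is removed. The centre of an even-length footprint
#' is `start + floor(length / 2)`.
#'
#' @param fp Footprint [interval_set()].
#' @param cuts A [scored_track()] of per-base DNase cut counts.
#' @param half_window_bp Half-window around the footprint centre (default
#'   100 bp).
#' @param skew_threshold Maximum tolerated single-position fraction of the
#'   window total (default 0.5).
#' @return List with `kept` and `removed` interval sets; both carry the
#'   diagnostic `skew_ratio` column (0 for an all-zero window, which is
#'   kept).
#' @export
filter_artefacts <- function(fp, cuts, half_window_bp = 100,
                             skew_threshold = 0.5) {
  fp <- as_interval_set(fp)
  n <- nrow(fp)
  ratio <- numeric(n)
  for (i in seq_len(n)) {
    len <- fp$end[i] - fp$start[i]
    centre <- fp$start[i] + floor(len / 2)
    v <- track_values(cuts, fp$chrom[i], centre - half_window_bp,
                      centre + half_window_bp + 1)
    tot <- sum(v)
    ratio[i] <- if (tot > 0) max(v) / tot else 0
  }
  fp$skew_ratio <- ratio
  removed <- ratio > skew_threshold
  list(
    kept = {x <- fp[!removed, , drop = FALSE]; rownames(x) <- NULL; x},
    removed = {x <- fp[removed, , drop = FALSE]; rownames(x) <- NULL; x}
  )
}

#' Threshold footprints by score centile
#'
#' Retains footprints whose score is at or above the given centile of the
#' score distribution of the input set (inverse-ECDF quantile, so centile
#' 0 keeps everything and centile 100 keeps only the maximal-score ties).
#'
#' @param fp Scored footprint [interval_set()].
#' @param centile Centile in `[0, 100]`.
#' @return The retained footprints.
#' @export
threshold_by_score <- function(fp, centile) {
  stopifnot(centile >= 0, centile <= 100)
  fp <- as_interval_set(fp)
  if (nrow(fp) == 0) return(fp)
  if (anyNA(fp$score)) stop("all footprints must carry scores")
  cutoff <- stats::quantile(fp$score, centile / 100, type = 1, names = FALSE)
  out <- fp[fp$score >= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full footprint quality-control pipeline
#'
#' Applies blacklist removal, autosome restriction, width bounds and the
#' artefact filter in order, with the (set-dependent) score-centile
#' threshold last. Returns per-stage counts for reporting.
#'
#' @param fp Footprint [interval_set()].
#' @param blacklist Blacklist [interval_set()] (or `NULL`).
#' @param autosomes Chromosomes to keep (or `NULL` to keep all).
#' @param cuts Optional [scored_track()] for the artefact filter.
#' @param min_bp,max_bp Width bounds.
#' @param half_window_bp,skew_threshold Artefact-filter parameters.
#' @param score_centile Optional final score-centile threshold.
#' @return List with `kept`, `removed_artefacts` and a `counts`
#'   `data.frame` (stage, n_in, n_out).
#' @export
footprint_qc <- function(fp, blacklist = NULL, autosomes = NULL, cuts = NULL,
                         min_bp = 11, max_bp = 22, half_window_bp = 100,
                         skew_threshold = 0.5, score_centile = NULL) {
  fp <- as_interval_set(fp)
  counts <- data.frame(stage = character(0), n_in = numeric(0),
                       n_out = numeric(0))
  note <- function(stage, n_in, n_out) {
    counts <<- rbind(counts, data.frame(stage = stage, n_in = n_in,
                                        n_out = n_out))
  }
  removed_artefacts <- interval_set()
  if (!is.null(blacklist)) {
    n0 <- nrow(fp); fp <- filter_blacklist(fp, blacklist)
    note("blacklist", n0, nrow(fp))
  }
  if (!is.null(autosomes)) {
    n0 <- nrow(fp); fp <- filter_autosomes(fp, autosomes)
    note("autosomes", n0, nrow(fp))
  }
  n0 <- nrow(fp); fp <- filter_width(fp, min_bp, max_bp)
  note("width", n0, nrow(fp))
  if (!is.null(cuts)) {
    n0 <- nrow(fp)
    parts <- filter_artefacts(fp, cuts, half_window_bp, skew_threshold)
    fp <- parts$kept
    removed_artefacts <- parts$removed
    note("artefacts", n0, nrow(fp))
  }
  if (!is.null(score_centile)) {
    n0 <- nrow(fp); fp <- threshold_by_score(fp, score_centile)
    note("score_centile", n0, nrow(fp))
  }
  list(kept = fp, removed_artefacts = removed_artefacts, counts = counts)
}
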